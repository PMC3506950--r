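#' Map taxonomy clades onto the reference phylogeny
#'
#' Each taxonomy clade (a named set of reference genomes, typically a genus
#' or a higher rank) is assigned the tree node whose descendant-genome set
#' maximises the Jaccard index `|A n B| / |A u B|` with the clade's genome
#' set.  Ties are broken toward the node with fewer descendant genomes (the
#' most specific clade), then by lexicographic node ID; the number of tied
#' optima is recorded.  Clades whose genomes overlap no node are returned
#' unmapped (`node_id = NA`).
#'
#' @param taxonomy A data frame with columns `clade_id` and `genome_id`
#'   (long format: one row per genome annotated to a clade).
#' @param ap An `annotated_phylo`.
#' @return A tibble with one row per clade: `clade_id`, `node_id`,
#'   `jaccard`, `tie_count`, `n_clade_genomes`, `n_node_genomes`.
#' @export
map_taxonomy_to_tree <- function(taxonomy, ap) {
  stopifnot(all(c("clade_id", "genome_id") %in% names(taxonomy)))
  tree <- ap$tree
  ids <- node_ids(tree)
  desc <- descendant_tips(tree)
  desc_sets <- purrr::map(desc, function(i) tree$tip.label[i])
  desc_n <- lengths(desc_sets)

  clades <- split(taxonomy$genome_id, taxonomy$clade_id)
  rows <- purrr::imap(clades, function(genomes, clade) {
    a <- unique(as.character(genomes))
    if (length(a) == 0L) {
      warn(sprintf("Clade '%s' has no genome annotations; left unmapped.", clade))
      return(tibble::tibble(clade_id = clade, node_id = NA_character_,
                            jaccard = NA_real_, tie_count = 0L,
                            n_clade_genomes = 0L, n_node_genomes = NA_integer_))
    }
    inter <- purrr::map_int(desc_sets, ~ length(intersect(a, .x)))
    jac <- inter / (length(a) + desc_n - inter)
    best <- max(jac)
    if (best <= 0) {
      return(tibble::tibble(clade_id = clade, node_id = NA_character_,
                            jaccard = NA_real_, tie_count = 0L,
                            n_clade_genomes = length(a),
                            n_node_genomes = NA_integer_))
    }
    cand <- which(jac == best)
    cand <- cand[order(desc_n[cand], ids[cand])]
    tibble::tibble(clade_id = clade, node_id = ids[cand[1]],
                   jaccard = best, tie_count = length(cand),
                   n_clade_genomes = length(a),
                   n_node_genomes = desc_n[cand[1]])
  })
  dplyr::bind_rows(rows)
}

#' Infer per-sample gene-family abundances from phylotype abundances
#'
#' A phylotype's contribution to gene family (KO) `i` in a sample is the
#' product of the reconstructed copy number at the phylotype's mapped tree
#' node and the phylotype's measured relative abundance; KO abundance is the
#' sum of contributions over all mapped phylotypes.  Phylotypes without a
#' mapping (or mapped to a node without a reconstructed vector) are skipped
#' and their abundance reported as lost mass per sample.
#'
#' @param taxa_table A taxon feature table (see [feature_table()]).
#' @param mapping Output of [map_taxonomy_to_tree()]; `clade_id` must cover
#'   the taxa-table feature IDs.
#' @param ap An `annotated_phylo` after [reconstruct_gene_content()].
#' @param renormalize Logical; when `TRUE` (default) each sample's KO vector
#'   is rescaled to sum to 1, so inferred gene tables feed the same QC and
#'   association path as taxa.  When `FALSE` raw copy-weighted sums are
#'   returned.
#' @return A feature table with `feature_kind = "gene"`.  The per-sample
#'   fraction of taxon abundance skipped for lack of a mapping is attached
#'   as the `skipped_mass` attribute (a tibble).
#' @export
#' @examples
#' # a phylotype at abundance 0.6 carrying 2 copies of a KO contributes 1.2
infer_ko_abundance <- function(taxa_table, mapping, ap, renormalize = TRUE) {
  if (is.null(ap$node_ko)) {
    abort("Run reconstruct_gene_content() before inferring abundances.")
  }
  abund <- feature_matrix(taxa_table)
  clades <- colnames(abund)
  map <- mapping[match(clades, mapping$clade_id), ]
  if (any(is.na(map$clade_id))) {
    abort(paste0("Phylotypes absent from the clade mapping: ",
                 toString(setdiff(clades, mapping$clade_id))))
  }
  has_vec <- !is.na(map$node_id) &
    map$node_id %in% rownames(ap$node_ko)[!is.na(ap$node_ko[, 1])]
  used <- clades[has_vec]
  if (length(used) == 0L) abort("No phylotype has a usable tree mapping.")

  G <- ap$node_ko[map$node_id[has_vec], , drop = FALSE]   # clades x KOs
  ko <- abund[, used, drop = FALSE] %*% G                 # samples x KOs

  total <- rowSums(abund, na.rm = TRUE)
  kept <- rowSums(abund[, used, drop = FALSE], na.rm = TRUE)
  skipped <- tibble::tibble(sample_id = rownames(abund),
                            skipped_mass = ifelse(total > 0,
                                                  1 - kept / total, 0))
  dead <- rownames(abund)[kept <= 0]
  if (length(dead)) {
    abort(paste0("No mapped phylotype abundance in sample(s): ",
                 toString(dead)))
  }
  if (renormalize) {
    sums <- rowSums(ko)
    zero <- sums <= 0
    if (any(zero)) {
      abort(paste0("Inferred KO totals are zero in sample(s): ",
                   toString(rownames(ko)[zero])))
    }
    ko <- ko / sums
  }
  out <- matrix_to_feature_table(ko, kind = "gene", relative = renormalize)
  attr(out, "skipped_mass") <- skipped
  out
}

#' Roll KO abundances up into gene-set abundances
#'
#' A deliberately naive rollup: each gene set's abundance is the mean (or
#' sum) of its member KOs' abundances in the sample.  This is a summary
#' convenience, not a parsimony-based pathway reconstruction.
#'
#' @param ko_table A gene feature table.
#' @param gene_set_map Data frame with columns `gene_set_id`, `ko_id`.
#' @param mode `"mean"` (default) or `"sum"`.
#' @return A feature table with `feature_kind = "gene_set"`.  Gene sets with
#'   no member KO present in `ko_table` are dropped with a warning.
#' @export
rollup_gene_sets <- function(ko_table, gene_set_map, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  m <- feature_matrix(ko_table)
  sets <- split(gene_set_map$ko_id, gene_set_map$gene_set_id)
  present <- purrr::map(sets, ~ intersect(unique(.x), colnames(m)))
  empty <- names(present)[lengths(present) == 0L]
  if (length(empty)) {
    warn(paste0("Gene sets with no member KO present were dropped: ",
                toString(empty)))
    present <- present[lengths(present) > 0L]
  }
  if (length(present) == 0L) abort("No gene set has any member KO present.")
  agg <- if (mode == "mean") {
    vapply(present, function(kos) rowMeans(m[, kos, drop = FALSE]),
           numeric(nrow(m)))
  } else {
    vapply(present, function(kos) rowSums(m[, kos, drop = FALSE]),
           numeric(nrow(m)))
  }
  agg <- matrix(agg, nrow = nrow(m),
                dimnames = list(rownames(m), names(present)))
  matrix_to_feature_table(agg, kind = "gene_set", relative = FALSE)
}
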