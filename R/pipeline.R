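#' Run the full analysis pipeline
#'
#' Orchestrates the stage sequence the analysis is built around:
#' QC the taxon table, compute alpha diversity, (optionally) infer the
#' metagenome from the phylogeny and roll it up into gene sets, QC the
#' inferred tables, and run the sparse multivariate association screen on
#' every feature kind.  The taxon-level and function-level summaries are
#' emitted side by side so the "fraction of functional features vs fraction
#' of clades significant" contrast is a first-class output.
#'
#' Inputs are validated before any stage runs; a stage failure aborts the
#' run with the manifest recording the completed stages.  Two runs with the
#' same inputs and config produce identical outputs (the boosting stream is
#' seeded from `config$seed`).
#'
#' @param features A taxon feature table.
#' @param meta A metadata tibble covering the feature-table samples.
#' @param config A [run_config()].
#' @param ap Optional [annotated_phylogeny()]; enables the inference stages.
#' @param taxonomy Optional clade-to-genome table (see
#'   [map_taxonomy_to_tree()]); required with `ap`.
#' @param gene_set_map Optional gene-set membership table (columns
#'   `gene_set_id`, `ko_id`); enables the gene-set rollup.
#' @param diversity Logical; append alpha-diversity columns to the metadata
#'   before association (they are responses in their own right but here are
#'   kept as descriptors).  Default `FALSE`.
#' @return A list of class `pipeline_run`: `associations` (named list of
#'   `assoc_result` per feature kind), `diversity` (tibble), `qc_reports`,
#'   `mapping`, `summary` (the [report_summary()] table), `manifest`,
#'   `config`.
#' @export
run_all <- function(features, meta, config = run_config(),
                    ap = NULL, taxonomy = NULL, gene_set_map = NULL,
                    diversity = FALSE) {
  if (!is.null(ap) && is.null(taxonomy)) {
    abort("`taxonomy` is required when an annotated phylogeny is supplied.")
  }
  meta <- align_samples(features, meta)
  manifest <- list()
  note <- function(stage, obj) {
    manifest[[length(manifest) + 1L]] <<- tibble::tibble(
      stage = stage, hash = rlang::hash(obj))
    obj
  }
  note("input_features", features)
  note("input_metadata", meta)

  div <- note("diversity", alpha_diversity(features))
  if (diversity) meta <- dplyr::left_join(meta, div, by = "sample_id")

  qc_taxa <- run_qc(features, meta, config)
  note("qc_taxa", qc_taxa$features)
  qc_reports <- list(taxon = qc_taxa$report)

  tables <- list(taxon = qc_taxa$features)
  mapping <- NULL
  if (!is.null(ap)) {
    if (is.null(ap$node_ko)) ap <- reconstruct_gene_content(ap)
    mapping <- note("clade_mapping", map_taxonomy_to_tree(taxonomy, ap))
    usable <- mapping$clade_id[!is.na(mapping$node_id)]
    taxa_for_inference <- features[c("sample_id",
                                     intersect(names(features), usable))]
    attr(taxa_for_inference, "feature_kind") <- "taxon"
    attr(taxa_for_inference, "relative") <- TRUE
    ko <- note("infer_ko",
               infer_ko_abundance(taxa_for_inference, mapping, ap,
                                  renormalize = config$renormalize))
    qc_ko <- run_qc(ko, qc_taxa$metadata, config)
    qc_reports$gene <- qc_ko$report
    tables$gene <- note("qc_gene", qc_ko$features)
    if (!is.null(gene_set_map)) {
      gs <- note("rollup_gene_sets", rollup_gene_sets(ko, gene_set_map))
      qc_gs <- run_qc(gs, qc_taxa$metadata, config)
      qc_reports$gene_set <- qc_gs$report
      tables$gene_set <- note("qc_gene_set", qc_gs$features)
    }
  }

  associations <- purrr::imap(tables, function(tbl, kind) {
    note(paste0("associate_", kind),
         associate_all(tbl, qc_taxa$metadata, config))
  })
  summary <- report_summary(associations, q_threshold = config$q_threshold)

  structure(
    list(associations = associations,
         diversity = div,
         qc_reports = qc_reports,
         mapping = mapping,
         summary = summary,
         manifest = dplyr::bind_rows(manifest),
         config = config),
    class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  print(x$summary)
  invisible(x)
}

#' Summarise significant associations per feature kind
#'
#' For each feature kind: the number of features tested, the number with at
#' least one association below the q threshold, and the percentage to one
#' decimal (rounded half away from zero) -- the style of contrast in which
#' 24 significant features of 200 tested reads as 12.0%.
#'
#' @param results A named list of `assoc_result` objects (or a single one).
#' @param q_threshold Significance threshold.  Default 0.25.
#' @return A tibble with columns `feature_kind`, `n_features_tested`,
#'   `n_significant`, `pct_significant`.
#' @export
#' @examples
#' # 24 of 200 -> 12.0; 21 of 295 -> 7.1
report_summary <- function(results, q_threshold = 0.25) {
  if (inherits(results, "assoc_result")) results <- list(results)
  purrr::map_dfr(results, function(r) {
    g <- glance(r, q_threshold = q_threshold)
    g[c("feature_kind", "n_features_tested", "n_significant",
        "pct_significant")]
  })
}

#' Plot the significant-fraction contrast across feature kinds
#'
#' @param summary A [report_summary()] tibble.
#' @return A ggplot bar chart of `pct_significant` per feature kind.
#' @export
plot_summary <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$feature_kind,
                               y = .data$pct_significant,
                               fill = .data$feature_kind)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "% features significant") +
    ggplot2::theme_minimal()
}

#' Plot per-sample diversity against a metadatum
#'
#' @param diversity Output of [alpha_diversity()].
#' @param meta Metadata tibble.
#' @param by Metadatum name to stratify by.
#' @param metric One of the diversity columns.  Default `"inv_simpson"`.
#' @return A ggplot (boxplots for categorical `by`, scatter for
#'   continuous).
#' @export
plot_diversity <- function(diversity, meta, by,
                           metric = c("inv_simpson", "chao1", "pielou",
                                      "richness")) {
  metric <- match.arg(metric)
  d <- dplyr::inner_join(diversity, meta, by = "sample_id")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data[[by]],
                                       y = .data[[metric]]))
  if (is.numeric(d[[by]])) {
    p + ggplot2::geom_point(alpha = 0.6) +
      ggplot2::geom_smooth(method = "lm", formula = y ~ x) +
      ggplot2::theme_minimal()
  } else {
    p + ggplot2::geom_boxplot() + ggplot2::theme_minimal()
  }
}
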