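#' Annotated reference phylogeny
#'
#' Couples a rooted `phylo` tree (leaves are reference genomes) with a
#' genome x KO copy-number matrix.  Copy numbers at leaves are integers
#' (0, 1, or multiple copies of a gene family in the genome annotation).
#'
#' @param tree A rooted `ape::phylo` object with non-negative branch lengths.
#'   Zero-length branches are allowed (weight 1); negative lengths are
#'   rejected.
#' @param ko Numeric matrix, rows named by genome (leaf) ID, columns by KO
#'   ID; non-negative integers.
#' @param allow_unannotated Logical; when `FALSE` (default) every leaf must
#'   appear in `ko`, otherwise missing leaves are flagged in
#'   `$unannotated`.
#'
#' @return A list of class `annotated_phylo` with elements `tree`, `ko`,
#'   `unannotated`, and (after [reconstruct_gene_content()]) `node_ko`.
#' @export
annotated_phylogeny <- function(tree, ko, allow_unannotated = FALSE) {
  if (!inherits(tree, "phylo")) abort("`tree` must be an ape 'phylo' object.")
  if (!ape::is.rooted(tree)) abort("The reference tree must be rooted.")
  if (is.null(tree$edge.length)) abort("The reference tree needs branch lengths.")
  if (any(tree$edge.length < 0)) abort("Negative branch lengths are not allowed.")
  if (is.null(rownames(ko)) || is.null(colnames(ko))) {
    abort("`ko` must have genome row names and KO column names.")
  }
  if (any(ko < 0)) abort("KO copy numbers must be non-negative.")
  if (any(abs(ko - round(ko)) > 1e-8)) {
    abort("Leaf KO copy numbers must be integers (0, 1 or multiple copies).")
  }
  missing <- setdiff(tree$tip.label, rownames(ko))
  if (length(missing) && !allow_unannotated) {
    abort(paste0("Tree leaves absent from the genome KO table: ",
                 toString(missing)))
  }
  structure(
    list(tree = tree,
         ko = ko[intersect(tree$tip.label, rownames(ko)), , drop = FALSE],
         unannotated = missing,
         node_ko = NULL),
    class = "annotated_phylo"
  )
}

#' Read an annotated phylogeny from Newick + TSV
#'
#' @param tree_path Path to a rooted Newick tree whose leaf labels are
#'   genome IDs.
#' @param genome_ko_path Path to a TSV genome x KO copy-number matrix
#'   (genomes as rows, first column genome ID).
#' @inheritParams annotated_phylogeny
#' @return An `annotated_phylo` object.
#' @export
read_annotated_tree <- function(tree_path, genome_ko_path,
                                allow_unannotated = FALSE) {
  tree <- ape::read.tree(tree_path)
  if (is.null(tree)) abort(sprintf("Could not parse Newick file '%s'.", tree_path))
  raw <- readr::read_tsv(genome_ko_path,
                         col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  ids <- raw[[1]]
  ko <- as.matrix(purrr::map_dfc(raw[-1], as.numeric))
  rownames(ko) <- ids
  annotated_phylogeny(tree, ko, allow_unannotated = allow_unannotated)
}

#' Write the genome x KO matrix of an annotated phylogeny to TSV
#' @param ap An `annotated_phylo`.
#' @param tree_path,genome_ko_path Output paths.
#' @return `ap`, invisibly.
#' @export
write_annotated_tree <- function(ap, tree_path, genome_ko_path) {
  ape::write.tree(ap$tree, tree_path)
  out <- tibble::as_tibble(as.data.frame(ap$ko, check.names = FALSE))
  out <- dplyr::bind_cols(tibble::tibble(genome_id = rownames(ap$ko)), out)
  readr::write_tsv(out, genome_ko_path, progress = FALSE)
  invisible(ap)
}

#' @export
print.annotated_phylo <- function(x, ...) {
  cat(sprintf("<annotated_phylo> %d leaves, %d internal nodes, %d KOs\n",
              ape::Ntip(x$tree), x$tree$Nnode, ncol(x$ko)))
  if (length(x$unannotated)) {
    cat(sprintf("  unannotated leaves: %s\n", toString(x$unannotated)))
  }
  cat(if (is.null(x$node_ko)) "  gene content not yet reconstructed\n"
      else "  ancestral gene content reconstructed\n")
  invisible(x)
}

# Stable string IDs for every node: tip label for leaves, node label (or
# "nodeN") for internal nodes.
node_ids <- function(tree) {
  n_tip <- ape::Ntip(tree)
  internal <- if (!is.null(tree$node.label) &&
                  !anyDuplicated(tree$node.label) &&
                  !any(tree$node.label == "")) {
    tree$node.label
  } else {
    paste0("node", seq_len(tree$Nnode) + n_tip)
  }
  c(tree$tip.label, internal)
}

# List of descendant tip index vectors for every node (tips included:
# a tip's descendant set is itself).
descendant_tips <- function(tree) {
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  kids <- vector("list", n_node)
  for (i in seq_len(n_tip)) kids[[i]] <- i
  # edges in postorder visit children before parents
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(eo))) {
    p <- eo[e, 1]; ch <- eo[e, 2]
    kids[[p]] <- c(kids[[p]], kids[[ch]])
  }
  kids
}

#' Distance-decay reconstruction weight
#'
#' The weight of a descendant genome in an ancestral gene-content average is
#' inversely exponential to its phylogenetic distance from the ancestor:
#' `w = 2^(-distance)`, so a genome one branch-length unit away counts half
#' as much as one at distance zero.
#'
#' @param distance Non-negative path branch length.
#' @return Weight in `(0, 1]`.
#' @export
#' @examples
#' reconstruction_weight(c(0, 1, 2))
reconstruction_weight <- function(distance) {
  if (any(distance < 0)) abort("Phylogenetic distance must be non-negative.")
  2^(-distance)
}

#' Reconstruct ancestral gene-content vectors
#'
#' Assigns every internal node of the reference phylogeny a KO copy-number
#' vector equal to the weighted average of its descendant leaves' genome
#' vectors, with weights `2^(-dist)` where `dist` is the branch-length path
#' distance from the node to the leaf.  Leaves keep their annotated vectors
#' unchanged.  Internal nodes whose descendant leaves are all unannotated
#' receive no vector and are flagged.
#'
#' @param ap An `annotated_phylo`.
#' @return `ap` with `$node_ko` (matrix over all nodes, rows named by node
#'   ID) and `$unreconstructed` (IDs of nodes without a vector) filled in.
#' @export
reconstruct_gene_content <- function(ap) {
  tree <- ap$tree
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  ids <- node_ids(tree)
  annotated <- match(rownames(ap$ko), tree$tip.label)
  dmat <- ape::dist.nodes(tree)
  desc <- descendant_tips(tree)

  node_ko <- matrix(NA_real_, nrow = n_node, ncol = ncol(ap$ko),
                    dimnames = list(ids, colnames(ap$ko)))
  node_ko[rownames(ap$ko), ] <- ap$ko
  unreconstructed <- character(0)

  for (g in (n_tip + 1):n_node) {
    leaves <- intersect(desc[[g]], annotated)
    if (length(leaves) == 0L) {
      unreconstructed <- c(unreconstructed, ids[g])
      next
    }
    w <- reconstruction_weight(dmat[g, leaves])
    vecs <- node_ko[tree$tip.label[leaves], , drop = FALSE]
    node_ko[g, ] <- colSums(vecs * w) / sum(w)
  }
  if (length(unreconstructed)) {
    warn(paste0("Nodes with no annotated descendant leaves: ",
                toString(unreconstructed)))
  }
  ap$node_ko <- node_ko
  ap$unreconstructed <- unreconstructed
  ap
}
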