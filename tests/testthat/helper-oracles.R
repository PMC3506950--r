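# Independent brute-force oracles and tiny fixture builders.  These stay
# deliberately naive: triple loops and exhaustive scans that the fast
# implementations are checked against.

# tiny 2-sample / 2-feature relative-abundance table
tiny_features <- function() {
  feature_table(tibble::tibble(sample_id = c("s1", "s2"),
                               a = c(0.6, 0.5), b = c(0.4, 0.5)))
}

# brute-force KO inference: explicit loop over (sample, phylotype, KO)
slow_infer <- function(taxa_table, mapping, ap, renormalize = TRUE) {
  abund <- feature_matrix(taxa_table)
  kos <- colnames(ap$node_ko)
  out <- matrix(0, nrow(abund), length(kos),
                dimnames = list(rownames(abund), kos))
  for (s in rownames(abund)) {
    for (g in colnames(abund)) {
      nd <- mapping$node_id[mapping$clade_id == g]
      if (length(nd) != 1 || is.na(nd)) next
      vec <- ap$node_ko[nd, ]
      if (anyNA(vec)) next
      for (i in kos) {
        out[s, i] <- out[s, i] + abund[s, g] * vec[i]
      }
    }
  }
  if (renormalize) out <- out / rowSums(out)
  out
}

# exhaustive Jaccard search over every tree node for one genome set
slow_best_node <- function(genomes, ap) {
  tree <- ap$tree
  ids <- phylofun:::node_ids(tree)
  desc <- phylofun:::descendant_tips(tree)
  best <- 0; hits <- character(0)
  for (nd in seq_along(ids)) {
    b <- tree$tip.label[desc[[nd]]]
    j <- length(intersect(genomes, b)) / length(union(genomes, b))
    if (j > best + 1e-12) { best <- j; hits <- ids[nd] }
    else if (abs(j - best) <= 1e-12 && j > 0) hits <- c(hits, ids[nd])
  }
  list(jaccard = best, nodes = hits)
}

# textbook BH step-up: find the largest k with p_(k) <= k/m * q by direct scan
slow_bh_reject <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i / m * q) k <- i
  if (k == 0) return(logical(m))
  p <= ps[k]
}

# a fixed 3-leaf annotated tree: ((A:1,B:2):0.5,C:3);
toy_tree <- function() {
  tree <- ape::read.tree(text = "((A:1,B:2)ab:0.5,C:3)root;")
  ko <- rbind(A = c(k1 = 1, k2 = 0),
              B = c(k1 = 0, k2 = 1),
              C = c(k1 = 2, k2 = 2))
  annotated_phylogeny(tree, ko)
}

# climb d ancestors from each leaf; returns a mapping tibble usable by
# infer_ko_abundance()
ancestor_mapping <- function(ap, d) {
  tree <- ap$tree
  ids <- phylofun:::node_ids(tree)
  parent <- integer(ape::Ntip(tree) + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- ape::Ntip(tree) + 1L
  node <- vapply(seq_len(ape::Ntip(tree)), function(tip) {
    nd <- tip
    for (k in seq_len(d)) {
      if (nd == root) break
      nd <- parent[nd]
    }
    nd
  }, integer(1))
  tibble::tibble(clade_id = tree$tip.label, node_id = ids[node],
                 jaccard = 1, tie_count = 1L)
}
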