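test_that("reconstruction weights decay as 2^(-distance)", {
  expect_equal(reconstruction_weight(0), 1)
  expect_equal(reconstruction_weight(1), 0.5)
  expect_equal(reconstruction_weight(2), 0.25)
  expect_error(reconstruction_weight(-0.1), "non-negative")
})

test_that("ancestral gene content is the hand-computed weighted leaf average", {
  # leaves at distances 1 and 2 with vectors (1,0), (0,1):
  # (0.5*(1,0) + 0.25*(0,1)) / 0.75 = (2/3, 1/3)
  ap <- reconstruct_gene_content(toy_tree())
  expect_equal(unname(ap$node_ko["ab", ]), c(2 / 3, 1 / 3), tolerance = 1e-12)
  # root: distances A = 1.5, B = 2.5, C = 3 -> weights 2^-1.5, 2^-2.5, 2^-3
  w <- 2^(-c(1.5, 2.5, 3))
  expected <- colSums(toy_tree()$ko * w) / sum(w)
  expect_equal(ap$node_ko["root", ], expected, tolerance = 1e-12)
  # leaves unchanged
  expect_equal(ap$node_ko["A", ], c(k1 = 1, k2 = 0))
})

test_that("reconstruction is exact for identical leaves and bounded by descendants", {
  tree <- ape::read.tree(text = "((A:0.3,B:1.7):0.2,(C:1,D:0):0.9);")
  v <- c(k1 = 3, k2 = 0, k3 = 1)
  same <- annotated_phylogeny(tree, rbind(A = v, B = v, C = v, D = v))
  rec <- reconstruct_gene_content(same)
  for (nd in rownames(rec$node_ko)) {
    expect_equal(rec$node_ko[nd, ], v, tolerance = 1e-12)
  }

  set.seed(31)
  for (rep in 1:20) {
    ref <- generate_annotated_tree(n_leaves = sample(4:8, 1), n_kos = 6,
                                   seed = rep)
    rec <- reconstruct_gene_content(ref$ap)
    desc <- phylofun:::descendant_tips(rec$tree)
    n_tip <- ape::Ntip(rec$tree)
    for (g in seq_len(rec$tree$Nnode) + n_tip) {
      leaves <- rec$tree$tip.label[desc[[g]]]
      lo <- apply(rec$ko[leaves, , drop = FALSE], 2, min)
      hi <- apply(rec$ko[leaves, , drop = FALSE], 2, max)
      val <- rec$node_ko[phylofun:::node_ids(rec$tree)[g], ]
      expect_true(all(val >= lo - 1e-9 & val <= hi + 1e-9))
    }
  }
})

test_that("single-leaf subtrees inherit the leaf vector regardless of distance", {
  tree <- ape::read.tree(text = "(A:5,(B:0.1,C:0.2):4);")
  ko <- rbind(A = c(k1 = 7), B = c(k1 = 1), C = c(k1 = 3))
  rec <- reconstruct_gene_content(annotated_phylogeny(tree, ko))
  # the cherry's ancestor only averages B and C; A's vector is at its leaf
  expect_equal(unname(rec$node_ko["A", ]), 7)
})

test_that("Jaccard clade mapping maximises overlap and breaks ties to specificity", {
  ap <- toy_tree()
  # identity: {A,B} is exactly clade ab
  tax <- tibble::tibble(clade_id = "gAB", genome_id = c("A", "B"))
  mp <- map_taxonomy_to_tree(tax, ap)
  expect_identical(mp$node_id, "ab")
  expect_equal(mp$jaccard, 1)

  # {A}: node A gives J = 1 beating ab (J = 1/2)
  mp2 <- map_taxonomy_to_tree(
    tibble::tibble(clade_id = "gA", genome_id = "A"), ap)
  expect_identical(mp2$node_id, "A")

  # absent genome -> unmapped
  mp3 <- map_taxonomy_to_tree(
    tibble::tibble(clade_id = "gX", genome_id = "g9"), ap)
  expect_true(is.na(mp3$node_id))

  # J = 2/3 node beats J = 1/2 node
  tree4 <- ape::read.tree(text = "(((g1:1,g2:1)x:1,g3:1)y:1,g4:1)r;")
  ko4 <- matrix(1, 4, 1, dimnames = list(paste0("g", 1:4), "k1"))
  ap4 <- annotated_phylogeny(tree4, ko4)
  mp4 <- map_taxonomy_to_tree(
    tibble::tibble(clade_id = "gen", genome_id = c("g1", "g2", "g3")), ap4)
  expect_identical(mp4$node_id, "y")
  expect_equal(mp4$jaccard, 1)
})

test_that("Jaccard mapping equals exhaustive search on random toy taxonomies", {
  set.seed(99)
  for (rep in 1:50) {
    ref <- generate_annotated_tree(n_leaves = sample(4:10, 1), n_kos = 3,
                                   seed = 1000 + rep)
    tips <- ref$ap$tree$tip.label
    genomes <- sample(tips, sample(1:length(tips), 1))
    mp <- map_taxonomy_to_tree(
      tibble::tibble(clade_id = "c", genome_id = genomes), ref$ap)
    oracle <- slow_best_node(genomes, ref$ap)
    expect_equal(mp$jaccard, oracle$jaccard, tolerance = 1e-12)
    expect_true(mp$node_id %in% oracle$nodes)
    expect_identical(mp$tie_count, length(oracle$nodes))
  }
})

test_that("KO inference is the abundance-weighted sum of mapped gene contents", {
  # phylotype A (0.6, 2 copies of k1) + B (0.4, 1 copy) -> raw KO1 = 1.6
  tree <- ape::read.tree(text = "(A:1,B:1)r;")
  ko <- rbind(A = c(k1 = 2, k2 = 0), B = c(k1 = 1, k2 = 1))
  ap <- reconstruct_gene_content(annotated_phylogeny(tree, ko))
  taxa <- feature_table(tibble::tibble(sample_id = "s1", A = 0.6, B = 0.4))
  mp <- map_taxonomy_to_tree(
    tibble::tibble(clade_id = c("A", "B"), genome_id = c("A", "B")), ap)
  raw <- infer_ko_abundance(taxa, mp, ap, renormalize = FALSE)
  expect_equal(feature_matrix(raw)["s1", "k1"], 1.6)
  expect_equal(feature_matrix(raw)["s1", "k2"], 0.4)

  # single phylotype at abundance 1 reproduces its node vector
  solo <- feature_table(tibble::tibble(sample_id = "s1", A = 1))
  expect_equal(feature_matrix(infer_ko_abundance(solo, mp, ap,
                                                 renormalize = FALSE))["s1", ],
               ap$node_ko["A", ])

  # renormalised output is a relative abundance table
  rel <- infer_ko_abundance(taxa, mp, ap)
  expect_equal(sum(feature_matrix(rel)), 1)
  expect_identical(feature_kind(rel), "gene")
})

test_that("inference matches the brute-force triple loop on random instances", {
  set.seed(5)
  for (rep in 1:15) {
    ref <- generate_annotated_tree(n_leaves = sample(3:8, 1),
                                   n_kos = sample(3:20, 1), seed = 300 + rep)
    genera <- ref$taxonomy[ref$taxonomy$rank == "genus", ]
    mp <- map_taxonomy_to_tree(genera, ref$ap)
    rec <- reconstruct_gene_content(ref$ap)
    n_s <- sample(1:5, 1)
    m <- matrix(rexp(n_s * nrow(mp)), n_s, nrow(mp),
                dimnames = list(paste0("s", 1:n_s), mp$clade_id))
    m <- m / rowSums(m)
    taxa <- matrix_to_feature_table(m)
    fast <- feature_matrix(infer_ko_abundance(taxa, mp, rec))
    slow <- slow_infer(taxa, mp, rec)
    expect_lt(max(abs(fast - slow[rownames(fast), colnames(fast)])), 1e-10)
  }
})

test_that("unmapped phylotypes are skipped with their mass reported", {
  ap <- reconstruct_gene_content(toy_tree())
  mp <- tibble::tibble(clade_id = c("A", "B", "ghost"),
                       node_id = c("A", "B", NA), jaccard = c(1, 1, NA),
                       tie_count = c(1L, 1L, 0L))
  taxa <- feature_table(tibble::tibble(sample_id = "s1", A = 0.5, B = 0.3,
                                       ghost = 0.2))
  out <- infer_ko_abundance(taxa, mp, ap, renormalize = FALSE)
  expect_equal(unname(attr(out, "skipped_mass")$skipped_mass), 0.2)
  # zero-abundance phylotype contributes nothing
  taxa2 <- feature_table(tibble::tibble(sample_id = "s1", A = 0.5, B = 0.3,
                                        ghost = 0))
  out2 <- infer_ko_abundance(taxa2, dplyr::mutate(mp, node_id = c("A", "B", "C")),
                             ap, renormalize = FALSE)
  out3 <- infer_ko_abundance(taxa2[c("sample_id", "A", "B")], mp[1:2, ], ap,
                             renormalize = FALSE)
  expect_equal(feature_matrix(out2), feature_matrix(out3))
})

test_that("gene-set rollup averages or sums member KOs and drops empty sets", {
  ko <- matrix_to_feature_table(
    matrix(c(0.2, 0.4, 0.4), 1, dimnames = list("s1", c("k1", "k2", "k3"))),
    kind = "gene")
  map <- tibble::tibble(gene_set_id = c("m1", "m1", "m2", "m3"),
                        ko_id = c("k1", "k2", "k3", "k9"))
  expect_warning(out <- rollup_gene_sets(ko, map), "m3")
  expect_equal(feature_matrix(out)["s1", "m1"], 0.3)
  expect_equal(feature_matrix(out)["s1", "m2"], 0.4)
  suppressWarnings(
    sums <- rollup_gene_sets(ko, map, mode = "sum"))
  expect_equal(feature_matrix(sums)["s1", "m1"], 0.6)
  expect_identical(feature_kind(out), "gene_set")
})
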