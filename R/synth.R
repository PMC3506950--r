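#' Synthetic cohort metadata
#'
#' Draws a mixed-type metadata table from a declarative specification.
#' Categorical columns are sampled from stated level probabilities,
#' optionally conditional on a previously generated column (to emulate
#' treatment probabilities that depend on disease status); continuous
#' columns are Gaussian.  Missingness is injected per column at a stated
#' rate.  Every generator in this module is a pure function of its
#' arguments and the seed.
#'
#' @param n_samples Number of samples (>= 2).
#' @param spec List of metadatum specs.  Each element is a list with
#'   `name`, `type` (`"categorical"`/`"continuous"`), and either `levels` +
#'   `probs` (probabilities summing to 1) or `mean` + `sd`; optional
#'   `missing_rate`; optional `cond_on` + `cond_probs` (a levels-of-parent x
#'   levels matrix of row-stochastic probabilities) for conditional
#'   categorical draws.  Defaults to [default_metadata_spec()], an
#'   IBD-cohort-like design.
#' @param seed Integer RNG seed.
#' @return A metadata tibble (`sample_id` plus typed columns).
#' @export
#' @examples
#' meta <- generate_metadata(20, seed = 1)
#' names(meta)
generate_metadata <- function(n_samples, spec = default_metadata_spec(),
                              seed = 1L) {
  if (n_samples < 2L) abort("Need at least 2 samples.")
  withr_seed(seed)
  out <- tibble::tibble(sample_id = sprintf("s%03d", seq_len(n_samples)))
  for (sp in spec) {
    nm <- sp$name
    if (sp$type == "categorical") {
      if (!is.null(sp$cond_on)) {
        parent <- as.character(out[[sp$cond_on]])
        if (is.null(parent)) abort(sprintf("'%s' conditions on unknown column '%s'.",
                                           nm, sp$cond_on))
        pm <- sp$cond_probs
        check_probs(pm, nm)
        v <- vapply(parent, function(pl) {
          sample(colnames(pm), 1L, prob = pm[pl, ])
        }, character(1), USE.NAMES = FALSE)
      } else {
        check_probs(matrix(sp$probs, nrow = 1,
                           dimnames = list(NULL, sp$levels)), nm)
        v <- sample(sp$levels, n_samples, replace = TRUE, prob = sp$probs)
      }
      v <- factor(v)
    } else {
      v <- rnorm(n_samples, sp$mean, sp$sd)
    }
    rate <- sp$missing_rate %||% 0
    if (rate > 0) v[runif(n_samples) < rate] <- NA
    out[[nm]] <- v
  }
  out
}

check_probs <- function(pm, nm) {
  if (any(pm < 0) || any(abs(rowSums(pm) - 1) > 1e-8)) {
    abort(sprintf("Probabilities for '%s' must be non-negative and sum to 1.", nm))
  }
}

#' @describeIn generate_metadata The default cohort design: disease status
#'   (healthy/CD/UC at the frequencies of a mixed IBD registry), stool vs
#'   biopsy sample type, Gaussian age, smoking history with a little
#'   missingness, and four treatments whose probabilities are conditional on
#'   disease (immunosuppressants concentrated in CD, mesalamine in UC,
#'   neither in healthy subjects).
#' @export
default_metadata_spec <- function() {
  trt <- function(name, p_h, p_cd, p_uc) {
    m <- rbind(healthy = c(p_h, 1 - p_h),
               CD = c(p_cd, 1 - p_cd),
               UC = c(p_uc, 1 - p_uc))
    colnames(m) <- c("yes", "no")
    list(name = name, type = "categorical", cond_on = "disease",
         cond_probs = m)
  }
  list(
    list(name = "disease", type = "categorical",
         levels = c("healthy", "CD", "UC"),
         probs = c(0.12, 0.54, 0.34)),
    list(name = "sample_type", type = "categorical",
         levels = c("stool", "biopsy"), probs = c(0.59, 0.41)),
    list(name = "age", type = "continuous", mean = 38, sd = 12),
    list(name = "smoking", type = "categorical",
         levels = c("never", "previous", "current"),
         probs = c(0.62, 0.27, 0.11), missing_rate = 0.01),
    trt("mesalamine", 0, 0.55, 0.77),
    trt("steroids", 0, 0.31, 0.37),
    trt("immunosuppressant", 0, 0.39, 0.16),
    trt("antibiotics", 0, 0.12, 0.13)
  )
}

#' Synthetic community abundances with planted metadata effects
#'
#' Generates a relative-abundance table under exactly the model the
#' association analysis fits: each feature's arcsine-sqrt-scale value is a
#' baseline mean plus planted linear metadata effects plus Gaussian noise,
#' back-transformed through `sin(z)^2` (with clamping to the valid range)
#' and renormalised per sample.  The planted truth is recorded before
#' renormalisation, together with the realised post-normalisation
#' coefficient of each effect.
#'
#' @param meta Metadata tibble from [generate_metadata()].
#' @param n_features Number of features.
#' @param effects Tibble of planted effects with columns `feature` (index or
#'   name), `metadatum`, `level` (`NA` for continuous), `beta`
#'   (arcsine-sqrt-scale).  Continuous metadata are z-scored before the
#'   effect is applied; missing metadata cells contribute no effect.
#' @param sigma Residual standard deviation on the arcsine-sqrt scale.
#' @param baseline Optional numeric vector of per-feature baseline means on
#'   the arcsine-sqrt scale; defaults to draws from `Uniform(0.3, 0.8)`,
#'   which keeps the arcsine-scale values well inside `[0, pi/2]` so
#'   clamping is negligible.
#' @param seed Integer RNG seed.
#' @return A list: `features` (a taxon feature table with per-sample sums
#'   of 1) and `truth` (class `synthetic_truth`: planted effects with
#'   realised coefficients, `sigma`, `baseline`, `clamped_fraction`,
#'   `seed`).
#' @export
generate_communities <- function(meta, n_features,
                                 effects = NULL, sigma = 0.1,
                                 baseline = NULL, seed = 1L) {
  n <- nrow(meta)
  withr_seed(seed)
  if (is.null(baseline)) baseline <- runif(n_features, 0.3, 0.8)
  stopifnot(length(baseline) == n_features)
  feat_ids <- sprintf("f%03d", seq_len(n_features))

  z <- matrix(rnorm(n * n_features, sd = sigma), n, n_features)
  z <- sweep(z, 2, baseline, "+")

  if (!is.null(effects) && nrow(effects)) {
    effects <- tibble::as_tibble(effects)
    if (is.numeric(effects$feature)) effects$feature <- feat_ids[effects$feature]
    for (k in seq_len(nrow(effects))) {
      e <- effects[k, ]
      j <- match(e$feature, feat_ids)
      if (is.na(j)) abort(sprintf("Planted effect references unknown feature '%s'.", e$feature))
      x <- planted_design(meta, e$metadatum, e$level)
      z[, j] <- z[, j] + e$beta * x
    }
  }

  clamped <- mean(z < 0 | z > pi / 2)
  if (clamped > 0.05) {
    warn(sprintf("%.1f%% of arcsine-scale values clamped to [0, pi/2].",
                 100 * clamped))
  }
  z <- pmin(pmax(z, 0), pi / 2)
  raw <- inv_arcsine_sqrt(z)
  rel <- raw / rowSums(raw)
  dimnames(rel) <- list(meta$sample_id, feat_ids)
  ft <- matrix_to_feature_table(rel, kind = "taxon", relative = TRUE)

  if (!is.null(effects) && nrow(effects)) {
    effects$beta_realized <- purrr::map_dbl(seq_len(nrow(effects)), function(k) {
      e <- effects[k, ]
      x <- planted_design(meta, e$metadatum, e$level)
      y <- arcsine_sqrt(rel[, e$feature])
      unname(coef(lm(y ~ x))[2])
    })
  }
  truth <- structure(
    list(effects = effects %||% tibble::tibble(
           feature = character(), metadatum = character(),
           level = character(), beta = double(), beta_realized = double()),
         sigma = sigma, baseline = setNames(baseline, feat_ids),
         clamped_fraction = clamped, seed = as.integer(seed)),
    class = "synthetic_truth")
  list(features = ft, truth = truth)
}

# Design vector for one planted effect: level indicator for categorical,
# z-score for continuous; missing cells contribute no effect.
planted_design <- function(meta, metadatum, level) {
  v <- meta[[metadatum]]
  if (is.null(v)) abort(sprintf("Planted effect references unknown metadatum '%s'.", metadatum))
  if (is.numeric(v)) {
    x <- (v - mean(v, na.rm = TRUE)) / sd(v, na.rm = TRUE)
    x[is.na(x)] <- 0
  } else {
    if (is.na(level)) abort(sprintf("Effect on categorical '%s' needs a `level`.", metadatum))
    x <- as.numeric(!is.na(v) & as.character(v) == level)
  }
  x
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d planted effects, sigma = %g, seed = %d\n",
              nrow(x$effects), x$sigma, x$seed))
  if (nrow(x$effects)) print(x$effects)
  invisible(x)
}

#' Dirichlet-gamma community generator (model mismatch check)
#'
#' An alternative generator that does not follow the analysis model:
#' per-sample abundances are independent Gamma draws normalised to
#' proportions (equivalently a Dirichlet), with planted effects acting
#' multiplicatively on the Gamma shape.  Useful for checking robustness of
#' the association screen when the generative model and the fitted model
#' disagree.
#'
#' @inheritParams generate_communities
#' @param shape Baseline Gamma shape per feature (scalar or vector);
#'   default 1.
#' @return Same structure as [generate_communities()] (no
#'   `beta_realized`; Dirichlet effects are not linear on the modelling
#'   scale).
#' @export
generate_communities_dm <- function(meta, n_features, effects = NULL,
                                    shape = 1, seed = 1L) {
  n <- nrow(meta)
  withr_seed(seed)
  feat_ids <- sprintf("f%03d", seq_len(n_features))
  sh <- matrix(rep_len(shape, n_features), n, n_features, byrow = TRUE)
  if (!is.null(effects) && nrow(effects)) {
    effects <- tibble::as_tibble(effects)
    if (is.numeric(effects$feature)) effects$feature <- feat_ids[effects$feature]
    for (k in seq_len(nrow(effects))) {
      e <- effects[k, ]
      x <- planted_design(meta, e$metadatum, e$level)
      j <- match(e$feature, feat_ids)
      sh[, j] <- sh[, j] * exp(e$beta * x)
    }
  }
  raw <- matrix(stats::rgamma(n * n_features, shape = sh, rate = 1), n, n_features)
  raw[raw == 0] <- 1e-12
  rel <- raw / rowSums(raw)
  dimnames(rel) <- list(meta$sample_id, feat_ids)
  truth <- structure(
    list(effects = effects %||% tibble::tibble(),
         sigma = NA_real_, baseline = NULL, clamped_fraction = 0,
         seed = as.integer(seed)),
    class = "synthetic_truth")
  list(features = matrix_to_feature_table(rel, kind = "taxon", relative = TRUE),
       truth = truth)
}

#' Synthetic annotated reference phylogeny and taxonomy
#'
#' Builds a coalescent-shaped rooted tree with exponential branch lengths
#' whose leaves are synthetic reference genomes, evolves KO copy numbers
#' from a root vector by per-branch gain/loss (so gene content correlates
#' with phylogeny), and derives a rank taxonomy whose clades are exact tree
#' clades (genus- and family-sized), optionally corrupted by mismatch
#' noise.
#'
#' @param n_leaves Number of reference genomes (>= 2).
#' @param n_kos Number of KO gene families.
#' @param seed Integer RNG seed.
#' @param mean_branch Mean of the exponential branch lengths.  Default 0.2.
#' @param gain_loss_rate Per-KO rate of +-1 copy-number jumps per unit
#'   branch length.  `0` freezes the root vector on every leaf.  Default 2.
#' @param mismatch Probability that a taxonomy clade has one genome removed
#'   from its annotation set (noise in the taxonomy-to-tree correspondence).
#'   Default 0.
#' @param genus_size Maximum clade size treated as a genus.  Default
#'   `max(2, ceiling(n_leaves / 5))`.
#' @return A list: `ap` (an [annotated_phylogeny()]) and `taxonomy` (tibble
#'   with `clade_id`, `rank`, `genome_id`).
#' @export
generate_annotated_tree <- function(n_leaves, n_kos, seed = 1L,
                                    mean_branch = 0.2, gain_loss_rate = 2,
                                    mismatch = 0,
                                    genus_size = max(2L, ceiling(n_leaves / 5))) {
  if (n_leaves < 2L) abort("Need at least 2 leaves.")
  withr_seed(seed)
  tree <- ape::rcoal(n_leaves, tip.label = sprintf("g%03d", seq_len(n_leaves)))
  tree$edge.length <- rexp(nrow(tree$edge), rate = 1 / mean_branch)
  tree$node.label <- sprintf("n%03d", seq_len(tree$Nnode))

  root_vec <- rpois(n_kos, 1)
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  vecs <- matrix(NA_real_, n_node, n_kos)
  root <- n_tip + 1L
  vecs[root, ] <- root_vec
  # preorder: parents before children
  cw <- ape::reorder.phylo(tree, "cladewise")
  pre <- cw$edge
  lens <- cw$edge.length
  for (e in seq_len(nrow(pre))) {
    parent <- pre[e, 1]; child <- pre[e, 2]
    v <- vecs[parent, ]
    p_change <- 1 - exp(-gain_loss_rate * lens[e])
    flip <- runif(n_kos) < p_change
    if (any(flip)) {
      v[flip] <- pmax(0, v[flip] + sample(c(-1, 1), sum(flip), replace = TRUE))
    }
    vecs[child, ] <- v
  }
  ko <- vecs[seq_len(n_tip), , drop = FALSE]
  dimnames(ko) <- list(tree$tip.label, sprintf("K%04d", seq_len(n_kos)))
  ap <- annotated_phylogeny(tree, ko)

  taxonomy <- derive_taxonomy(tree, genus_size)
  if (mismatch > 0) {
    taxonomy <- taxonomy |>
      dplyr::group_by(.data$clade_id) |>
      dplyr::group_modify(function(d, key) {
        if (nrow(d) >= 2 && runif(1) < mismatch) d[-sample(nrow(d), 1), ] else d
      }) |>
      dplyr::ungroup()
  }
  list(ap = ap, taxonomy = taxonomy)
}

# Rank taxonomy whose clades are exact tree clades: one species-level clade
# per leaf, genera are maximal clades of at most genus_size leaves, families
# maximal clades of at most 3 * genus_size, one domain-level clade spans the
# whole tree.
derive_taxonomy <- function(tree, genus_size) {
  n_tip <- ape::Ntip(tree)
  desc <- descendant_tips(tree)
  sizes <- lengths(desc)
  parent <- integer(n_tip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- n_tip + 1L
  maximal_under <- function(cap) {
    which(vapply(seq_along(sizes), function(nd) {
      sizes[nd] <= cap && (nd == root || sizes[parent[nd]] > cap)
    }, logical(1)))
  }
  rank_rows <- function(nodes, rank) {
    purrr::imap_dfr(nodes, function(nd, i) {
      tibble::tibble(clade_id = sprintf("%s_%02d", rank, i), rank = rank,
                     genome_id = tree$tip.label[desc[[nd]]])
    })
  }
  dplyr::bind_rows(
    tibble::tibble(clade_id = tree$tip.label, rank = "species",
                   genome_id = tree$tip.label),
    rank_rows(maximal_under(genus_size), "genus"),
    rank_rows(maximal_under(3L * genus_size), "family"),
    tibble::tibble(clade_id = "domain_01", rank = "domain",
                   genome_id = tree$tip.label)
  )
}

#' True paired metagenome for validating inference
#'
#' The oracle the inference is scored against: each sample's true KO
#' profile is the abundance-weighted mixture of the TRUE leaf genome
#' vectors (never reconstructed ancestors), mirroring paired
#' whole-community shotgun sequencing of the same community.
#'
#' @param taxa_table A taxon feature table whose features are phylotypes.
#' @param ap An [annotated_phylogeny()].
#' @param composition Tibble with columns `clade_id`, `genome_id`, `weight`
#'   describing which leaves (and in what proportion) make up each
#'   phylotype.  Defaults to the identity map (phylotypes are leaves).
#' @param renormalize Match the inference output scale (default `TRUE`).
#' @return A gene feature table of true KO profiles.
#' @export
generate_paired_metagenome <- function(taxa_table, ap, composition = NULL,
                                       renormalize = TRUE) {
  abund <- feature_matrix(taxa_table)
  if (is.null(composition)) {
    composition <- tibble::tibble(clade_id = colnames(abund),
                                  genome_id = colnames(abund), weight = 1)
  }
  missing <- setdiff(composition$genome_id, rownames(ap$ko))
  if (length(missing)) {
    abort(paste0("Composition references unannotated genomes: ",
                 toString(missing)))
  }
  G <- matrix(0, ncol(abund), ncol(ap$ko),
              dimnames = list(colnames(abund), colnames(ap$ko)))
  for (cl in unique(composition$clade_id)) {
    rows <- composition[composition$clade_id == cl, ]
    w <- rows$weight / sum(rows$weight)
    G[cl, ] <- colSums(ap$ko[rows$genome_id, , drop = FALSE] * w)
  }
  ko <- abund %*% G
  if (renormalize) ko <- ko / rowSums(ko)
  matrix_to_feature_table(ko, kind = "gene", relative = renormalize)
}

#' Per-sample Spearman correlation of inferred vs true KO profiles
#'
#' The validation protocol for the inference step: for each sample, the
#' Spearman rank correlation between the inferred KO abundances and the
#' paired true profile, over the KOs shared by both tables.
#'
#' @param inferred,truth Gene feature tables sharing samples and KOs.
#' @return A tibble with columns `sample_id`, `spearman`.
#' @export
spearman_validation <- function(inferred, truth) {
  mi <- feature_matrix(inferred)
  mt <- feature_matrix(truth)
  kos <- intersect(colnames(mi), colnames(mt))
  samples <- intersect(rownames(mi), rownames(mt))
  if (length(kos) < 3L) abort("Fewer than 3 shared KOs; nothing to correlate.")
  tibble::tibble(
    sample_id = samples,
    spearman = purrr::map_dbl(samples, function(s) {
      cor(mi[s, kos], mt[s, kos], method = "spearman")
    }))
}

#' Generate a complete synthetic study
#'
#' Presets bundling the generators into ready-to-analyse datasets:
#' * `"assoc-null"` — cohort metadata and communities with no planted
#'   effects (for false-discovery checks);
#' * `"assoc-planted"` — as above plus planted disease/treatment/age
#'   effects of magnitude `beta` on the arcsine-sqrt scale;
#' * `"inference-toy"` — an annotated phylogeny, taxonomy, leaf-level
#'   communities and their true paired metagenomes (for validating the
#'   inference path).
#'
#' @param preset One of `"assoc-null"`, `"assoc-planted"`,
#'   `"inference-toy"`.
#' @param n_samples Number of samples.  Default 200.
#' @param n_features Number of community features.  Default 50.
#' @param beta Planted effect size (arcsine-sqrt scale) for
#'   `"assoc-planted"`.  Default 0.3.
#' @param sigma Residual SD on the arcsine-sqrt scale.  Default 0.1.
#' @param n_leaves,n_kos Tree size for `"inference-toy"`.
#' @param seed Integer RNG seed.
#' @return A list with the generated pieces (`features`, `metadata`,
#'   `truth`; for the inference preset also `ap`, `taxonomy`,
#'   `true_metagenome`).
#' @export
simulate_preset <- function(preset = c("assoc-null", "assoc-planted",
                                       "inference-toy"),
                            n_samples = 200, n_features = 50,
                            beta = 0.3, sigma = 0.1,
                            n_leaves = 30, n_kos = 40, seed = 1L) {
  preset <- match.arg(preset)
  meta <- generate_metadata(n_samples, seed = derive_seed(seed, 1))
  if (preset == "assoc-null") {
    com <- generate_communities(meta, n_features, effects = NULL,
                                sigma = sigma, seed = derive_seed(seed, 2))
    return(list(features = com$features, metadata = meta, truth = com$truth))
  }
  if (preset == "assoc-planted") {
    effects <- tibble::tibble(
      feature = c(1L, 2L, 3L),
      metadatum = c("disease", "antibiotics", "age"),
      level = c("CD", "yes", NA),
      beta = c(beta, -beta, beta / 2))
    com <- generate_communities(meta, n_features, effects = effects,
                                sigma = sigma, seed = derive_seed(seed, 2))
    return(list(features = com$features, metadata = meta, truth = com$truth))
  }
  # inference-toy: communities over tree leaves
  ref <- generate_annotated_tree(n_leaves, n_kos, seed = derive_seed(seed, 3))
  withr_seed(derive_seed(seed, 4))
  abund <- matrix(stats::rgamma(n_samples * n_leaves, shape = 0.5), n_samples,
                  n_leaves)
  abund <- abund / rowSums(abund)
  dimnames(abund) <- list(sprintf("s%03d", seq_len(n_samples)),
                          ref$ap$tree$tip.label)
  taxa <- matrix_to_feature_table(abund, kind = "taxon", relative = TRUE)
  list(features = taxa,
       metadata = meta[seq_len(min(n_samples, nrow(meta))), ],
       ap = ref$ap, taxonomy = ref$taxonomy,
       true_metagenome = generate_paired_metagenome(taxa, ref$ap))
}

# set.seed without touching the caller's RNG state beyond this call chain;
# generators own their stream.
withr_seed <- function(seed) {
  set.seed(as.integer(seed))
  invisible(seed)
}
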