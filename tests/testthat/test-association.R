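noise_meta <- function(n, p = 10, seed = 1) {
  set.seed(seed)
  meta <- tibble::tibble(sample_id = sprintf("s%03d", seq_len(n)))
  for (j in seq_len(p)) meta[[paste0("x", j)]] <- rnorm(n)
  meta
}

test_that("boosting selects a strong linear driver and is seed-deterministic", {
  meta <- noise_meta(200, seed = 8)
  y <- 0.5 * meta$x1 + rnorm(200, 0, 0.05)
  sel <- boost_select(y, meta, run_config(), seed = 8)
  expect_true(sel$selected[sel$metadatum == "x1"])
  expect_gt(sel$fraction[sel$metadatum == "x1"],
            max(sel$fraction[sel$metadatum != "x1"]))
  expect_equal(sum(sel$fraction), 1)  # every iteration splits somewhere

  again <- boost_select(y, meta, run_config(), seed = 8)
  expect_identical(sel$fraction, again$fraction)

  # degenerate threshold: nothing reaches a fraction of 1 under pure noise
  null_sel <- boost_select(rnorm(200), meta,
                           run_config(select_fraction = 1.0), seed = 8)
  expect_false(any(null_sel$selected))
})

test_that("boosting agrees with an independent gradient-boosting engine on the driver", {
  meta <- noise_meta(200, p = 6, seed = 21)
  y <- 0.4 * meta$x2 + rnorm(200, 0, 0.05)
  sel <- boost_select(y, meta, run_config(), seed = 21)
  X <- as.matrix(meta[paste0("x", 1:6)])
  bst <- suppressWarnings(
    xgboost::xgboost(data = X, label = y, nrounds = 1000, max_depth = 1,
                     eta = 0.01, subsample = 0.5, nthread = 1,
                     objective = "reg:squarederror", verbose = 0))
  dt <- xgboost::xgb.model.dt.tree(model = bst)
  counts <- table(factor(dt$Feature[dt$Feature != "Leaf"],
                         levels = colnames(X)))
  xgb_frac <- as.numeric(counts) / 1000
  # both engines put the bulk of their splits on the true driver
  expect_identical(sel$metadatum[which.max(sel$fraction)], "x2")
  expect_identical(colnames(X)[which.max(xgb_frac)], "x2")
  expect_equal(sel$fraction[sel$metadatum == "x2"], max(xgb_frac),
               tolerance = 0.15)
})

test_that("removing a never-split metadatum leaves other selection fractions unchanged", {
  meta <- noise_meta(150, p = 4, seed = 13)
  meta$flat <- rep(1, 150)  # constant: no valid split exists
  y <- 0.5 * meta$x1 + rnorm(150, 0, 0.1)
  with_flat <- boost_select(y, meta, run_config(), seed = 13)
  without <- boost_select(y, meta[setdiff(names(meta), "flat")],
                          run_config(), seed = 13)
  keep <- with_flat$metadatum != "flat"
  expect_equal(with_flat$fraction[keep], without$fraction)
  expect_equal(with_flat$fraction[!keep], 0)
})

test_that("the linear model recovers coefficients and closed-form group differences", {
  meta <- noise_meta(100, p = 2, seed = 3)
  y <- 1 + 0.3 * meta$x1
  rec <- suppressWarnings(fit_feature_model(y, meta, c("x1"), feature_id = "f"))
  expect_equal(rec$coefficient, 0.3, tolerance = 1e-8)
  expect_lt(rec$p, 1e-12)

  # single binary metadatum: coefficient = group-mean difference
  set.seed(4)
  grp <- factor(sample(c("ctl", "trt"), 100, replace = TRUE,
                       prob = c(0.6, 0.4)))
  meta2 <- tibble::tibble(sample_id = meta$sample_id, grp = grp)
  y2 <- rnorm(100) + 0.5 * (grp == "trt")
  rec2 <- fit_feature_model(y2, meta2, "grp", feature_id = "f")
  expect_identical(rec2$reference, "ctl")  # most frequent level
  expect_equal(rec2$coefficient,
               mean(y2[grp == "trt"]) - mean(y2[grp == "ctl"]),
               tolerance = 1e-10)

  expect_error(fit_feature_model(y[1:3], meta[1:3, ], c("x1", "x2")),
               "Too few samples")
})

test_that("null coefficients give uniform p-values", {
  set.seed(12)
  pvals <- replicate(200, {
    x <- rnorm(120)
    y <- rnorm(120)
    meta <- tibble::tibble(sample_id = as.character(1:120), x1 = x)
    fit_feature_model(y, meta, "x1")$p
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("within-factor Bonferroni multiplies by level count and caps at 1", {
  rec <- tibble::tibble(
    feature = c(rep("f1", 3), "f2", "f3", "f3", "f3"),
    metadatum = c(rep("smoking", 3), "age", rep("grp", 3)),
    level = c("a", "b", "c", NA, "a", "b", "c"),
    p = c(0.02, 0.5, 0.01, 0.04, 0.5, 0.6, 0.7))
  adj <- adjust_within_factor(rec)
  expect_equal(adj$p_adj[1:3], c(0.06, 1, 0.03))
  expect_equal(adj$p_adj[4], 0.04)  # continuous untouched
  expect_equal(adj$p_adj[5:7], c(1, 1, 1))
  expect_true(all(adj$p_adj >= adj$p))
})

test_that("BH q-values match worked examples and the reference implementation", {
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_qvalues(0.2), 0.2)
  expect_equal(bh_qvalues(rep(1, 5)), rep(1, 5))

  set.seed(77)
  for (i in 1:200) {
    p <- runif(sample(1:60, 1))^sample(1:3, 1)
    q <- bh_qvalues(p)
    expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-14)
    expect_true(all(diff(q[order(p)]) >= -1e-14))  # monotone in p
    # rejection sets agree with the textbook step-up scan
    for (alpha in c(0.05, 0.25)) {
      expect_identical(q <= alpha + 1e-14, slow_bh_reject(p, alpha))
    }
  }
})

test_that("associate_all is deterministic and flags features with no selection", {
  sim <- simulate_preset("assoc-planted", n_samples = 60, n_features = 8,
                         seed = 19)
  qc <- run_qc(sim$features, sim$metadata, run_config(seed = 19))
  cfg <- run_config(seed = 19, boost_rounds = 300)
  r1 <- associate_all(qc$features, qc$metadata, cfg)
  r2 <- associate_all(qc$features, qc$metadata, cfg)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$selection, r2$selection)

  # the shared-design fast path equals the per-feature public API
  m <- feature_matrix(qc$features)
  sel1 <- boost_select(arcsine_sqrt(m[, 1]), qc$metadata, cfg,
                       seed = phylofun:::derive_seed(cfg$seed, 1))
  inline <- r1$selection[r1$selection$feature == colnames(m)[1], ]
  expect_equal(inline$fraction, sel1$fraction)

  expect_s3_class(tidy(r1), "tbl_df")
  g <- glance(r1)
  expect_identical(g$n_features_tested, 8L)
  ord <- order(r1$records$p_adj)
  expect_true(all(diff(r1$records$q[ord]) >= -1e-12))
  expect_true(all(r1$records$q >= r1$records$p_adj - 1e-12))
  plt <- autoplot(r1)
  expect_s3_class(plt, "ggplot")
})

test_that("planted effects are recovered within two standard errors", {
  hits <- 0; tested <- 0
  for (s in 1:15) {
    meta <- noise_meta(150, p = 5, seed = 400 + s)
    y <- 0.25 + 0.3 * meta$x3 + rnorm(150, 0, 0.1)
    sel <- boost_select(y, meta, run_config(), seed = 400 + s)
    if (!sel$selected[sel$metadatum == "x3"]) next
    rec <- fit_feature_model(y, meta, sel$metadatum[sel$selected])
    row <- rec[rec$metadatum == "x3", ]
    tested <- tested + 1
    hits <- hits + (abs(row$coefficient - 0.3) <= 2 * row$stderr)
  }
  expect_gte(tested, 14)
  expect_gte(hits / tested, 0.9)
})
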