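cfg <- run_config(seed = 11)

test_that("metadata filter drops >10% missing and invariant columns, strict boundary", {
  n <- 100
  meta <- tibble::tibble(
    sample_id = sprintf("s%03d", 1:n),
    keep = rnorm(n),
    missing11 = replace(rnorm(n), 1:11, NA),
    missing10 = replace(rnorm(n), 1:10, NA),
    constant = factor(rep("never", n)))
  out <- filter_metadata(meta, cfg)
  expect_setequal(names(out$metadata), c("sample_id", "keep", "missing10"))
  expect_setequal(out$report$dropped_metadata$metadatum,
                  c("missing11", "constant"))
  expect_match(out$report$dropped_metadata$reason[
    out$report$dropped_metadata$metadatum == "constant"], "invariant")
  expect_error(filter_metadata(meta["sample_id"], cfg), "no metadata")
})

test_that("low-abundance filter applies the 0.001 / 90% rule with its boundary", {
  m <- cbind(
    zero = rep(0, 10),
    ok = rep(0.002, 10),
    boundary = c(rep(0.0005, 9), 0.5),   # low in exactly 9/10 >= 90% -> drop
    kept = c(rep(0.0005, 8), 0.3, 0.3))  # low in 8/10 < 90% -> keep
  rownames(m) <- sprintf("s%02d", 1:10)
  ft <- matrix_to_feature_table(m)
  out <- filter_features(ft, cfg)
  expect_setequal(setdiff(names(out$features), "sample_id"), c("ok", "kept"))
  expect_setequal(out$report$dropped_features$feature, c("zero", "boundary"))
})

test_that("outer-fence outlier removal matches hand-computed type-7 fences", {
  # {1,2,3,4,100}: Q1 = 2, Q3 = 4 (linear interpolation), fences [-4, 10]
  m <- cbind(spiky = c(1, 2, 3, 4, 100) / 200,
             flat = rep(5, 5) / 200,
             mild = c(2, 3, 4, 5, 6) / 200)
  rownames(m) <- sprintf("s%d", 1:5)
  out <- remove_outliers(matrix_to_feature_table(m), cfg)
  flagged <- out$report$outliers
  expect_identical(nrow(flagged), 1L)
  expect_identical(flagged$feature, "spiky")
  expect_identical(flagged$sample_id, "s5")
  expect_equal(unname(flagged$value), 0.5)
  expect_true(is.na(feature_matrix(out$features)["s5", "spiky"]))
  # constant feature: fences undefined, untouched, noted
  expect_equal(feature_matrix(out$features)[, "flat"], m[, "flat"])
  expect_match(paste(out$report$notes, collapse = " "), "flat")
  # in-fence feature untouched
  expect_equal(feature_matrix(out$features)[, "mild"], m[, "mild"])
})

test_that("imputation fills feature means and adds the explicit NA factor level", {
  m <- cbind(f1 = c(0.1, NA, 0.3), f2 = c(0.2, 0.2, 0.2))
  rownames(m) <- c("s1", "s2", "s3")
  meta <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                         grp = factor(c("yes", NA, "no")),
                         age = c(30, NA, 50))
  out <- impute_missing(matrix_to_feature_table(m, relative = FALSE), meta, cfg)
  expect_equal(feature_matrix(out$features)["s2", "f1"], 0.2)
  expect_identical(levels(out$metadata$grp), c("no", "yes", "NA"))
  expect_identical(as.character(out$metadata$grp[2]), "NA")
  expect_equal(out$metadata$age[2], 40)
  expect_identical(nrow(out$report$imputed), 3L)

  # per-sample-mean reading behind the switch
  alt <- impute_missing(matrix_to_feature_table(m, relative = FALSE), meta,
                        run_config(impute = "sample"))
  expect_equal(feature_matrix(alt$features)["s2", "f1"], 0.2)  # mean of s2 row

  m_na <- cbind(f1 = c(NA_real_, NA_real_), f2 = c(0.1, 0.2))
  rownames(m_na) <- c("s1", "s2")
  all_na <- matrix_to_feature_table(m_na, relative = FALSE)
  expect_error(impute_missing(all_na, meta[1:2, ], cfg), "entirely missing")

  complete <- tibble::tibble(sample_id = c("s1", "s2", "s3"), age = c(1, 2, 3))
  noop <- impute_missing(matrix_to_feature_table(m[, 2, drop = FALSE],
                                                 relative = FALSE),
                         complete, cfg)
  expect_identical(nrow(noop$report$imputed), 0L)
  expect_equal(noop$metadata, complete)
})

test_that("arcsine-sqrt transform hits its landmarks and is monotone", {
  expect_equal(arcsine_sqrt(0), 0)
  expect_equal(arcsine_sqrt(1), pi / 2)
  expect_equal(arcsine_sqrt(0.25), pi / 6)
  expect_error(arcsine_sqrt(-0.01), "out of")
  expect_error(arcsine_sqrt(1.001), "out of")
  expect_equal(arcsine_sqrt(1 + 5e-7), pi / 2)  # renormalisation slack clamped

  x <- sort(runif(100))
  fx <- arcsine_sqrt(x)
  expect_true(all(diff(fx) > 0))
  z <- seq(0, pi / 2, length.out = 50)
  expect_equal(arcsine_sqrt(sin(z)^2), z, tolerance = 1e-12)
})

test_that("the QC chain is idempotent and its report replays exactly", {
  sim <- simulate_preset("assoc-planted", n_samples = 80, n_features = 20,
                         seed = 5)
  once <- run_qc(sim$features, sim$metadata, cfg)
  twice <- run_qc(once$features, once$metadata, cfg)
  expect_equal(feature_matrix(twice$features), feature_matrix(once$features))
  expect_equal(twice$metadata, once$metadata)

  replayed <- replay_qc(once$report, sim$features, sim$metadata)
  expect_equal(feature_matrix(replayed$features), feature_matrix(once$features))
  expect_equal(replayed$metadata, once$metadata)
})
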