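#' Boosted covariate selection for one feature
#'
#' Fits a gradient-boosted stump ensemble (squared-error loss, depth-1
#' trees) of the transformed feature abundance on all metadata, and reports
#' for each metadatum the fraction of boosting iterations whose tree split
#' on it.  Metadata at or above `config$select_fraction` (default 1%) are
#' selected for the linear model.  Categorical metadata enter as one-hot
#' indicator columns; splits on any level count toward the metadatum.
#'
#' @param response Numeric response vector (typically arcsine-sqrt
#'   transformed abundance), aligned with `meta` rows.
#' @param meta Metadata tibble (`sample_id` plus typed columns), no missing
#'   values (run [impute_missing()] first).
#' @param config A [run_config()]; the boosting hyperparameters and the
#'   selection threshold live here.
#' @param seed Integer seed for the boosting subsample stream; defaults to
#'   `config$seed`.
#' @return A tibble with columns `metadatum`, `fraction`, `selected`, plus
#'   attributes `seed` and `n_fitted`.
#' @export
boost_select <- function(response, meta, config = run_config(),
                         seed = config$seed) {
  design <- boosting_design(meta)
  if (ncol(design$X) == 0L) abort("No metadata columns to select from.")
  if (length(response) != nrow(design$X)) {
    abort("`response` and `meta` are not row-aligned.")
  }
  if (length(response) < 10L) abort("Need at least 10 samples for selection.")
  fit <- boost_stumps_cpp(design$X, response, config$boost_rounds,
                          config$learning_rate, config$subsample,
                          as.integer(seed))
  frac <- tapply(fit$split_count / config$boost_rounds, design$column_meta, sum)
  out <- tibble::tibble(
    metadatum = design$metadata,
    fraction = as.numeric(frac[design$metadata]),
    selected = .data$fraction >= config$select_fraction
  )
  attr(out, "seed") <- as.integer(seed)
  attr(out, "n_fitted") <- fit$n_fitted
  out
}

# One-hot design matrix for boosting: continuous columns as-is, every level
# of a categorical column as an indicator.  column_meta maps matrix columns
# back to metadata names.
boosting_design <- function(meta) {
  cols <- setdiff(names(meta), "sample_id")
  blocks <- purrr::map(cols, function(nm) {
    v <- meta[[nm]]
    if (anyNA(v)) abort(sprintf("Metadata column '%s' has missing values; impute first.", nm))
    if (is.numeric(v)) {
      m <- matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, nm))
    } else {
      f <- factor(v)
      m <- vapply(levels(f), function(l) as.numeric(f == l),
                  numeric(length(f)))
      colnames(m) <- paste0(nm, "=", levels(f))
    }
    m
  })
  X <- do.call(cbind, blocks)
  list(X = X,
       column_meta = rep(cols, vapply(blocks, ncol, integer(1))),
       metadata = cols)
}

# Factor with the most frequent level as reference (ties: first by
# frequency table order), recorded so coefficients are interpretable.
relevel_most_frequent <- function(v) {
  f <- factor(v)
  ref <- names(sort(table(f), decreasing = TRUE))[1]
  stats::relevel(f, ref = ref)
}

#' Linear model of a transformed feature on selected metadata
#'
#' Ordinary least squares of the (arcsine-sqrt transformed) abundance on an
#' intercept plus the boosting-selected metadata.  Categorical metadata are
#' dummy-coded against their most frequent level; each non-reference level
#' yields one association record.  Aliased (rank-deficient) columns are
#' dropped with a warning.
#'
#' @inheritParams boost_select
#' @param selected Character vector of metadata names to include.
#' @param feature_id Feature label carried into the records.
#' @return A tibble of association records: `feature`, `metadatum`, `level`
#'   (`NA` for continuous), `reference`, `n`, `coefficient`, `stderr`, `p`.
#' @export
fit_feature_model <- function(response, meta, selected,
                              feature_id = "feature") {
  if (length(selected) == 0L) abort("`selected` must name at least one metadatum.")
  missing <- setdiff(selected, names(meta))
  if (length(missing)) abort(paste0("Unknown metadata: ", toString(missing)))
  df <- meta[selected]
  refs <- purrr::map_chr(selected, function(nm) {
    if (is.numeric(df[[nm]])) return(NA_character_)
    f <- relevel_most_frequent(df[[nm]])
    df[[nm]] <<- f
    levels(f)[1]
  })
  names(refs) <- selected
  df$.y <- response
  n_par <- 1L + sum(purrr::map_int(selected, function(nm) {
    if (is.numeric(df[[nm]])) 1L else nlevels(df[[nm]]) - 1L
  }))
  if (length(response) <= n_par) {
    abort(sprintf("Too few samples (%d) for %d model parameters.",
                  length(response), n_par))
  }
  fit <- lm(.y ~ ., data = df)
  cf <- summary(fit)$coefficients
  aliased <- names(which(is.na(coef(fit))))
  if (length(aliased)) {
    warn(paste0("Aliased terms dropped from '", feature_id, "': ",
                toString(aliased)))
  }
  # map design columns back to (metadatum, level)
  assign_idx <- attr(model.matrix(fit), "assign")
  term_names <- attr(fit$terms, "term.labels")
  mm_cols <- colnames(model.matrix(fit))
  keep <- which(assign_idx > 0 & mm_cols %in% rownames(cf))
  purrr::map_dfr(keep, function(k) {
    nm <- term_names[assign_idx[k]]
    col <- mm_cols[k]
    lev <- if (is.numeric(df[[nm]])) NA_character_ else substring(col, nchar(nm) + 1L)
    row <- cf[col, ]
    tibble::tibble(
      feature = feature_id, metadatum = nm, level = lev,
      reference = refs[[nm]], n = length(response),
      coefficient = row[["Estimate"]], stderr = row[["Std. Error"]],
      p = row[["Pr(>|t|)"]])
  })
}

#' Within-factor Bonferroni adjustment
#'
#' Within each (feature, metadatum) pair, each level's p-value is multiplied
#' by the number of non-reference levels tested, capped at 1.  Continuous
#' metadata contribute a single record and are unchanged.
#'
#' @param records Association records from [fit_feature_model()].
#' @return `records` with a `p_adj` column.
#' @export
adjust_within_factor <- function(records) {
  records |>
    dplyr::group_by(.data$feature, .data$metadatum) |>
    dplyr::mutate(p_adj = pmin(1, .data$p * dplyr::n())) |>
    dplyr::ungroup()
}

#' Benjamini-Hochberg step-up q-values
#'
#' The textbook step-up procedure over one pool of m p-values:
#' `q_(i) = min_{j >= i} p_(j) * m / j` on the sorted p-values, capped at 1.
#' q-values are monotone non-decreasing in p.
#'
#' @param p Numeric vector of p-values.
#' @return q-values in the original order.
#' @export
#' @examples
#' bh_qvalues(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_qvalues <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' @describeIn bh_qvalues Attach a global `q` column to association records,
#'   computed over the level-adjusted p-values of the whole pool.
#' @param records Association records with a `p_adj` column.
#' @export
adjust_global_bh <- function(records) {
  records$q <- bh_qvalues(records$p_adj)
  records
}

#' Associate every feature with sample metadata
#'
#' The full sparse multivariate screen: per feature, arcsine-sqrt transform
#' the abundance, select covariates by boosting, fit the composite linear
#' model on the selected metadata, Bonferroni-adjust within each factor,
#' then apply one global Benjamini-Hochberg correction across all
#' (feature, metadatum, level) records of the run.  Per-feature failures are
#' recorded and the run continues.
#'
#' @param features A QC'd, imputed feature table.
#' @param meta QC'd, imputed metadata aligned on `sample_id`.
#' @param config A [run_config()].
#' @param transform Logical; apply [arcsine_sqrt()] to abundances (default
#'   `TRUE`; set `FALSE` if the response is already on a modelling scale).
#' @return An object of class `assoc_result`: a list with `records` (tibble
#'   incl. `q`), `selection` (per feature x metadatum boosting fractions),
#'   `skipped` (features with no selected metadata or a failed fit),
#'   `feature_kind`, `n_features_tested`, and the `config` used.  Use
#'   [tidy()], [glance()] and [autoplot()] on it.
#' @export
associate_all <- function(features, meta, config = run_config(),
                          transform = TRUE) {
  meta <- align_samples(features, meta)
  m <- feature_matrix(features)
  if (anyNA(m)) abort("Feature table has missing values; run impute_missing() first.")
  design <- boosting_design(meta)  # validates metadata completeness

  resp <- if (transform) apply(m, 2, arcsine_sqrt) else m
  feats <- colnames(m)
  skipped <- tibble::tibble(feature = character(), reason = character())
  selections <- vector("list", length(feats))
  records <- vector("list", length(feats))
  col_group <- factor(design$column_meta, levels = design$metadata)

  for (i in seq_along(feats)) {
    f <- feats[i]
    # same computation as boost_select(), sharing one design matrix
    fit <- boost_stumps_cpp(design$X, resp[, i], config$boost_rounds,
                            config$learning_rate, config$subsample,
                            derive_seed(config$seed, i))
    frac <- as.numeric(tapply(fit$split_count / config$boost_rounds,
                              col_group, sum))
    sel <- tibble::tibble(metadatum = design$metadata, fraction = frac,
                          selected = frac >= config$select_fraction)
    selections[[i]] <- dplyr::mutate(sel, feature = f, .before = 1)
    chosen <- sel$metadatum[sel$selected]
    if (length(chosen) == 0L) {
      skipped <- dplyr::add_row(skipped, feature = f,
                                reason = "no metadata selected by boosting")
      next
    }
    rec <- tryCatch(
      fit_feature_model(resp[, i], meta, chosen, feature_id = f),
      error = function(e) {
        skipped <<- dplyr::add_row(skipped, feature = f,
                                   reason = conditionMessage(e))
        NULL
      })
    records[[i]] <- rec
  }
  records <- dplyr::bind_rows(records)
  if (nrow(records)) {
    records <- adjust_global_bh(adjust_within_factor(records))
  } else {
    records <- tibble::tibble(
      feature = character(), metadatum = character(), level = character(),
      reference = character(), n = integer(), coefficient = double(),
      stderr = double(), p = double(), p_adj = double(), q = double())
  }
  sel_tbl <- dplyr::bind_rows(selections) |>
    dplyr::left_join(
      dplyr::distinct(records[c("feature", "metadatum", "q")]) |>
        dplyr::group_by(.data$feature, .data$metadatum) |>
        dplyr::summarise(min_q = min(.data$q), .groups = "drop"),
      by = c("feature", "metadatum"))
  structure(
    list(records = records,
         selection = sel_tbl,
         skipped = skipped,
         feature_kind = feature_kind(features),
         n_features_tested = length(feats),
         config = config),
    class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<assoc_result> %s features: %d tested, %d records, %d significant (q < %.2f, %.1f%%)\n",
    x$feature_kind, g$n_features_tested, nrow(x$records),
    g$n_significant, x$config$q_threshold, g$pct_significant))
  invisible(x)
}

#' Tidy an association result
#'
#' @param x An `assoc_result`.
#' @param ... Unused.
#' @return The association records: one row per (feature, metadatum, level)
#'   with `coefficient`, `stderr`, `p`, `p_adj` (within-factor Bonferroni)
#'   and `q` (global Benjamini-Hochberg).
#' @export
tidy.assoc_result <- function(x, ...) x$records

#' One-row summary of an association result
#'
#' Reports the headline contrast quantity: how many of the tested features
#' carry at least one association below the configured q threshold.
#'
#' @inheritParams tidy.assoc_result
#' @param q_threshold Significance threshold; defaults to the run config's.
#' @return A one-row tibble: `feature_kind`, `n_features_tested`,
#'   `n_records`, `n_significant`, `pct_significant`.
#' @export
glance.assoc_result <- function(x, q_threshold = x$config$q_threshold, ...) {
  sig <- x$records |>
    dplyr::filter(.data$q < q_threshold) |>
    dplyr::distinct(.data$feature)
  tibble::tibble(
    feature_kind = x$feature_kind,
    n_features_tested = x$n_features_tested,
    n_records = nrow(x$records),
    n_significant = nrow(sig),
    pct_significant = round_half_up(100 * nrow(sig) /
                                      max(1L, x$n_features_tested), 1))
}

#' Volcano plot of association records
#'
#' @param object An `assoc_result`.
#' @param q_threshold Significance line; defaults to the run config's.
#' @param ... Unused.
#' @return A ggplot: coefficient against `-log10(q)`, coloured by metadatum,
#'   with the q threshold drawn as a dashed line.
#' @export
autoplot.assoc_result <- function(object,
                                  q_threshold = object$config$q_threshold,
                                  ...) {
  rec <- object$records
  ggplot2::ggplot(rec, ggplot2::aes(x = .data$coefficient,
                                    y = -log10(pmax(.data$q, 1e-300)),
                                    colour = .data$metadatum)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(q_threshold), linetype = "dashed") +
    ggplot2::labs(
      x = "coefficient (arcsine-sqrt scale)",
      y = expression(-log[10](q)),
      title = sprintf("Associations (%s features)", object$feature_kind)) +
    ggplot2::theme_minimal()
}

# round half away from zero at `digits` decimals (the convention used for
# reported percentages)
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}
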