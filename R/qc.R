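#' Pre-modeling quality control
#'
#' The association analysis assumes QC'd inputs: uninformative metadata
#' dropped, rare features dropped, per-feature outliers blanked, missing
#' cells imputed, and proportions variance-stabilised.  Each step returns the
#' transformed table together with a [qc_report] that records exactly what
#' changed and why; [replay_qc()] re-applies a report to the original input.
#'
#' The chain runs in the order
#' `filter_metadata()` -> `filter_features()` -> `remove_outliers()` ->
#' `impute_missing()`, so outlying cells never leak into imputed means.
#'
#' @name qc
NULL

new_qc_report <- function() {
  structure(
    list(
      dropped_metadata = tibble::tibble(metadatum = character(),
                                        reason = character()),
      dropped_features = tibble::tibble(feature = character(),
                                        reason = character()),
      outliers = tibble::tibble(sample_id = character(), feature = character(),
                                value = double()),
      imputed = tibble::tibble(sample_id = character(), item = character(),
                               kind = character(), value = character()),
      notes = character(),
      quantile_type = 7L
    ),
    class = "qc_report"
  )
}

merge_qc_reports <- function(...) {
  reps <- list(...)
  out <- new_qc_report()
  for (nm in c("dropped_metadata", "dropped_features", "outliers", "imputed")) {
    out[[nm]] <- dplyr::bind_rows(purrr::map(reps, nm))
  }
  out$notes <- unlist(purrr::map(reps, "notes"))
  out
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  cat(sprintf("  metadata dropped: %d\n", nrow(x$dropped_metadata)))
  cat(sprintf("  features dropped: %d\n", nrow(x$dropped_features)))
  cat(sprintf("  outlier cells:    %d\n", nrow(x$outliers)))
  cat(sprintf("  cells imputed:    %d\n", nrow(x$imputed)))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Drop uninformative metadata columns
#'
#' Removes metadata with more than `max_missing` (default 10%) of values
#' missing, and metadata that do not vary over the non-missing samples.
#' The missingness rule is a strict inequality: a column missing in exactly
#' 10% of samples is retained.
#'
#' @param meta Metadata tibble.
#' @param config A [run_config()].
#' @return A list with elements `metadata` and `report`.
#' @export
filter_metadata <- function(meta, config = run_config()) {
  cols <- setdiff(names(meta), "sample_id")
  if (length(cols) == 0L) abort("Metadata table has no metadata columns.")
  report <- new_qc_report()
  drop <- character(0)
  for (nm in cols) {
    v <- meta[[nm]]
    frac_missing <- mean(is.na(v))
    if (frac_missing > config$max_missing) {
      drop <- c(drop, nm)
      report$dropped_metadata <- dplyr::add_row(
        report$dropped_metadata, metadatum = nm,
        reason = sprintf("missing fraction %.3f > %.2f", frac_missing,
                         config$max_missing))
    } else if (dplyr::n_distinct(v[!is.na(v)]) <= 1L) {
      drop <- c(drop, nm)
      report$dropped_metadata <- dplyr::add_row(
        report$dropped_metadata, metadatum = nm, reason = "invariant")
    }
  }
  kept <- setdiff(cols, drop)
  if (length(kept) == 0L) abort("All metadata columns were dropped; nothing to model.")
  list(metadata = meta[c("sample_id", kept)], report = report)
}

#' Drop very-low-abundance features
#'
#' A feature is removed when its abundance is below `low_abundance`
#' (default 0.001) in at least `prevalence` (default 90%) of samples,
#' computed over non-missing values.
#'
#' @param features A feature table.
#' @inheritParams filter_metadata
#' @return A list with elements `features` and `report`.
#' @export
filter_features <- function(features, config = run_config()) {
  m <- feature_matrix(features)
  frac_low <- colMeans(m < config$low_abundance, na.rm = TRUE)
  drop <- colnames(m)[frac_low >= config$prevalence]
  report <- new_qc_report()
  if (length(drop)) {
    report$dropped_features <- tibble::tibble(
      feature = drop,
      reason = sprintf("< %g in >= %d%% of samples", config$low_abundance,
                       round(100 * config$prevalence)))
  }
  kept <- setdiff(colnames(m), drop)
  if (length(kept) == 0L) abort("All features fell below the abundance filter.")
  out <- features[c("sample_id", kept)]
  attr(out, "feature_kind") <- feature_kind(features)
  attr(out, "relative") <- attr(features, "relative")
  list(features = out, report = report)
}

#' Blank outer-fence outliers
#'
#' Per feature, values below `Q1 - k * IQR` or above `Q3 + k * IQR`
#' (`k = fence_multiplier`, default 3; quartiles by linear interpolation,
#' R quantile type 7) are set to missing and logged.  Features with a zero
#' or undefined IQR are left untouched with a note.
#'
#' @inheritParams filter_features
#' @return A list with elements `features` and `report`.
#' @export
remove_outliers <- function(features, config = run_config()) {
  m <- feature_matrix(features)
  report <- new_qc_report()
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    ok <- !is.na(v)
    if (sum(ok) < 4L) {
      report$notes <- c(report$notes, sprintf(
        "feature '%s': fewer than 4 non-missing values, outlier fences skipped",
        colnames(m)[j]))
      next
    }
    q <- quantile(v[ok], c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    if (iqr == 0) {
      report$notes <- c(report$notes, sprintf(
        "feature '%s': zero IQR, outlier fences undefined", colnames(m)[j]))
      next
    }
    lo <- q[1] - config$fence_multiplier * iqr
    hi <- q[2] + config$fence_multiplier * iqr
    bad <- which(ok & (v < lo | v > hi))
    if (length(bad)) {
      report$outliers <- dplyr::bind_rows(
        report$outliers,
        tibble::tibble(sample_id = rownames(m)[bad],
                       feature = colnames(m)[j], value = v[bad]))
      m[bad, j] <- NA_real_
    }
  }
  out <- matrix_to_feature_table(m, kind = feature_kind(features),
                                 relative = isTRUE(attr(features, "relative")))
  list(features = out, report = report)
}

#' Impute missing feature and metadata values
#'
#' Missing abundances are replaced by the feature's mean over non-missing
#' samples (default) or, with `config$impute = "sample"`, by the sample's
#' mean over non-missing features.  Missing categorical metadata become an
#' explicit `"NA"` factor level; missing continuous metadata take the column
#' mean.
#'
#' @param features A feature table (missing cells allowed).
#' @param meta Metadata tibble aligned on `sample_id`.
#' @inheritParams filter_metadata
#' @return A list with elements `features`, `metadata`, `report`.
#' @export
impute_missing <- function(features, meta, config = run_config()) {
  m <- feature_matrix(features)
  report <- new_qc_report()
  miss <- which(is.na(m), arr.ind = TRUE)
  if (nrow(miss)) {
    all_missing <- colnames(m)[colSums(!is.na(m)) == 0L]
    if (length(all_missing)) {
      abort(paste0("Feature(s) entirely missing, cannot impute: ",
                   toString(all_missing)))
    }
    fill <- if (config$impute == "feature") {
      colMeans(m, na.rm = TRUE)[miss[, 2]]
    } else {
      rowMeans(m, na.rm = TRUE)[miss[, 1]]
    }
    report$imputed <- tibble::tibble(
      sample_id = rownames(m)[miss[, 1]],
      item = colnames(m)[miss[, 2]],
      kind = "feature",
      value = as.character(fill))
    m[miss] <- fill
  }
  for (nm in setdiff(names(meta), "sample_id")) {
    v <- meta[[nm]]
    idx <- which(is.na(v))
    if (!length(idx)) next
    if (is.numeric(v)) {
      mu <- mean(v, na.rm = TRUE)
      v[idx] <- mu
      report$imputed <- dplyr::bind_rows(report$imputed, tibble::tibble(
        sample_id = meta$sample_id[idx], item = nm, kind = "metadatum",
        value = as.character(mu)))
    } else {
      v <- factor(v, levels = c(levels(factor(v)), "NA"))
      v[idx] <- "NA"
      report$imputed <- dplyr::bind_rows(report$imputed, tibble::tibble(
        sample_id = meta$sample_id[idx], item = nm, kind = "metadatum",
        value = "NA"))
    }
    meta[[nm]] <- v
  }
  out <- matrix_to_feature_table(m, kind = feature_kind(features),
                                 relative = isTRUE(attr(features, "relative")))
  list(features = out, metadata = meta, report = report)
}

#' Arcsine-square-root transform for proportions
#'
#' The variance-stabilising transform for proportion data:
#' `asin(sqrt(x))`, mapping `[0, 1]` onto `[0, pi/2]` and strictly
#' increasing.  Values above 1 by at most `1e-6` (floating-point slack from
#' renormalisation) are clamped to 1.
#'
#' @param x Numeric vector of proportions in `[0, 1]`.
#' @return `asin(sqrt(x))`.
#' @export
#' @examples
#' arcsine_sqrt(c(0, 0.25, 1))  # 0, pi/6, pi/2
arcsine_sqrt <- function(x) {
  bad <- which(!is.na(x) & (x < 0 | x > 1 + 1e-6))
  if (length(bad)) {
    abort(sprintf("Proportion out of [0, 1]: %g", x[bad[1]]))
  }
  asin(sqrt(pmin(x, 1)))
}

# Back-transform from the arcsine-sqrt scale to a proportion.
inv_arcsine_sqrt <- function(z) sin(z)^2

#' Run the full QC chain
#'
#' Applies [filter_metadata()], [filter_features()], [remove_outliers()] and
#' [impute_missing()] in that order and merges the reports.
#'
#' @inheritParams impute_missing
#' @return A list with elements `features`, `metadata`, `report`.
#' @export
run_qc <- function(features, meta, config = run_config()) {
  meta <- align_samples(features, meta)
  s1 <- filter_metadata(meta, config)
  s2 <- filter_features(features, config)
  s3 <- remove_outliers(s2$features, config)
  s4 <- impute_missing(s3$features, s1$metadata, config)
  report <- merge_qc_reports(s1$report, s2$report, s3$report, s4$report)
  report$config <- config  # thresholds and seed travel with the report
  list(features = s4$features,
       metadata = s4$metadata,
       report = report)
}

#' Replay a QC report on the original input
#'
#' A [qc_report] fully determines the transformation from input to output:
#' this function re-applies the recorded drops, outlier blanks and
#' imputations and must reproduce [run_qc()]'s output exactly.
#'
#' @param report A `qc_report`.
#' @inheritParams impute_missing
#' @return A list with elements `features` and `metadata`.
#' @export
replay_qc <- function(report, features, meta) {
  meta <- align_samples(features, meta)
  meta <- meta[setdiff(names(meta), report$dropped_metadata$metadatum)]
  features <- features[setdiff(names(features), report$dropped_features$feature)]
  m <- feature_matrix(features)
  if (nrow(report$outliers)) {
    m[cbind(match(report$outliers$sample_id, rownames(m)),
            match(report$outliers$feature, colnames(m)))] <- NA_real_
  }
  imp_f <- dplyr::filter(report$imputed, .data$kind == "feature")
  if (nrow(imp_f)) {
    m[cbind(match(imp_f$sample_id, rownames(m)),
            match(imp_f$item, colnames(m)))] <- as.numeric(imp_f$value)
  }
  imp_m <- dplyr::filter(report$imputed, .data$kind == "metadatum")
  for (nm in unique(imp_m$item)) {
    rows <- dplyr::filter(imp_m, .data$item == nm)
    v <- meta[[nm]]
    i <- match(rows$sample_id, meta$sample_id)
    if (is.numeric(v)) {
      v[i] <- as.numeric(rows$value)
    } else {
      v <- factor(v, levels = c(levels(factor(v)), "NA"))
      v[i] <- rows$value
    }
    meta[[nm]] <- v
  }
  list(features = matrix_to_feature_table(m, kind = feature_kind(features),
                                          relative = isTRUE(attr(features, "relative"))),
       metadata = meta)
}
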