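#' Alpha-diversity metrics
#'
#' Per-sample community summaries: inverse Simpson diversity (the effective
#' number of equally common taxa), bias-corrected Chao1 richness, and Pielou
#' evenness (Shannon entropy over log richness).  [alpha_diversity()] applies
#' all three across a feature table; the scalar functions are exported for
#' direct use.
#'
#' @name ecology
NULL

#' @describeIn ecology Inverse Simpson diversity `1 / sum(p_i^2)`.  The
#'   input is normalised to proportions internally, so the metric is
#'   invariant to rescaling.
#' @param abundances Non-negative numeric vector with at least one positive
#'   entry.
#' @export
#' @examples
#' inverse_simpson(rep(1, 4))   # 4
#' pielou(c(0.5, 0.5))          # 1
#' chao1(c(1, 1, 2))            # 3.5
inverse_simpson <- function(abundances) {
  if (any(abundances < 0, na.rm = TRUE)) abort("Abundances must be non-negative.")
  tot <- sum(abundances, na.rm = TRUE)
  if (!is.finite(tot) || tot <= 0) abort("All-zero abundance vector.")
  p <- abundances[!is.na(abundances)] / tot
  1 / sum(p^2)
}

#' @describeIn ecology Bias-corrected Chao1 richness
#'   `S_obs + F1 * (F1 - 1) / (2 * (F2 + 1))`, where `F1` and `F2` are the
#'   singleton and doubleton counts.  Counts must be integers; set
#'   `pseudo_counts = TRUE` to convert relative abundances by dividing by
#'   the smallest positive value and rounding.
#' @param counts Non-negative integer count vector.
#' @param pseudo_counts Logical; convert non-integer abundances to
#'   pseudo-counts before estimating.  Off by default because Chao1 is a
#'   count-based estimator.
#' @export
chao1 <- function(counts, pseudo_counts = FALSE) {
  counts <- counts[!is.na(counts)]
  if (any(counts < 0)) abort("Counts must be non-negative.")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    if (!pseudo_counts) {
      abort("Non-integer input; pass pseudo_counts = TRUE to convert abundances.")
    }
    pos <- counts[counts > 0]
    counts <- round(counts / min(pos))
  }
  counts <- round(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' @describeIn ecology Pielou evenness: Shannon entropy (natural log, over
#'   positive proportions) divided by `log` of observed richness.  Undefined
#'   (`NA`) when fewer than two features are present.
#' @export
pielou <- function(abundances) {
  if (any(abundances < 0, na.rm = TRUE)) abort("Abundances must be non-negative.")
  p <- abundances[!is.na(abundances) & abundances > 0]
  s <- length(p)
  if (s <= 1L) return(NA_real_)
  p <- p / sum(p)
  h <- -sum(p * log(p))
  h / log(s)
}

#' @describeIn ecology Compute all metrics for every sample of a feature
#'   table.
#' @param features A feature table (see [feature_table()]).
#' @return For `alpha_diversity()`: a tibble with columns `sample_id`,
#'   `inv_simpson`, `chao1`, `pielou`, `richness`.  `pielou` is `NA` for
#'   single-feature communities.
#' @export
alpha_diversity <- function(features, pseudo_counts = TRUE) {
  m <- feature_matrix(features)
  tibble::tibble(
    sample_id = rownames(m),
    inv_simpson = apply(m, 1, inverse_simpson),
    chao1 = apply(m, 1, chao1, pseudo_counts = pseudo_counts),
    pielou = apply(m, 1, pielou),
    richness = apply(m, 1, function(v) sum(v > 0, na.rm = TRUE))
  )
}

#' Append diversity columns to a metadata table
#'
#' Convenience for testing community ecology as a response: the diversity
#' metrics become continuous metadata columns that can be modelled like any
#' other.
#'
#' @inheritParams alpha_diversity
#' @param meta Metadata tibble.
#' @return `meta` with `inv_simpson`, `chao1`, `pielou`, `richness` joined
#'   on `sample_id`.
#' @export
add_diversity <- function(meta, features, pseudo_counts = TRUE) {
  dplyr::left_join(meta, alpha_diversity(features, pseudo_counts),
                   by = "sample_id")
}
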