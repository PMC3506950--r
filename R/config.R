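#' Analysis run configuration
#'
#' Collects every threshold the pipeline applies, together with the RNG seed
#' and the boosting hyperparameters, so a run is fully described by one
#' object.  All downstream functions that take a `config` argument accept the
#' output of this function.
#'
#' @param low_abundance Relative-abundance cutoff below which a value counts
#'   as "very low" for the prevalence filter.  Default `0.001`.
#' @param prevalence Fraction of samples that must be below `low_abundance`
#'   for a feature to be dropped.  Default `0.90`.
#' @param fence_multiplier Multiplier of the interquartile range defining the
#'   outer fences used for per-feature outlier removal.  Default `3`.
#' @param max_missing Maximum tolerated fraction of missing values in a
#'   metadata column; columns strictly above this are dropped.  Default `0.10`.
#' @param select_fraction Minimum fraction of boosting iterations in which a
#'   metadatum must be split upon to enter the linear model.  Default `0.01`.
#' @param q_threshold False-discovery-rate threshold used when summarising
#'   significant associations.  Default `0.25`.
#' @param seed Integer RNG seed recorded in all outputs.
#' @param boost_rounds Number of boosting iterations (depth-1 regression
#'   trees).  Default `1000`.
#' @param learning_rate Shrinkage applied to each boosted stump.  Default
#'   `0.01`.
#' @param subsample Fraction of samples drawn (without replacement) for each
#'   boosting iteration.  Default `0.5`.
#' @param impute Either `"feature"` (replace a missing abundance by that
#'   feature's mean over non-missing samples, the default) or `"sample"`
#'   (replace it by the sample's mean over non-missing features).
#' @param renormalize Logical; renormalise inferred gene abundances to
#'   per-sample relative abundances.  Default `TRUE`.
#'
#' @return A list of class `run_config`.
#' @export
#' @examples
#' cfg <- run_config(seed = 42)
#' cfg$q_threshold
run_config <- function(low_abundance = 0.001,
                       prevalence = 0.90,
                       fence_multiplier = 3,
                       max_missing = 0.10,
                       select_fraction = 0.01,
                       q_threshold = 0.25,
                       seed = 1L,
                       boost_rounds = 1000L,
                       learning_rate = 0.01,
                       subsample = 0.5,
                       impute = c("feature", "sample"),
                       renormalize = TRUE) {
  impute <- match.arg(impute)
  stopifnot(
    low_abundance >= 0,
    prevalence > 0, prevalence <= 1,
    fence_multiplier > 0,
    max_missing >= 0, max_missing < 1,
    select_fraction >= 0, select_fraction <= 1,
    q_threshold > 0, q_threshold <= 1,
    boost_rounds >= 1,
    learning_rate > 0, learning_rate <= 1,
    subsample > 0, subsample <= 1
  )
  seed <- as.integer(seed)
  if (is.na(seed)) abort("`seed` must be an integer.")
  structure(
    list(
      low_abundance = low_abundance,
      prevalence = prevalence,
      fence_multiplier = fence_multiplier,
      max_missing = max_missing,
      select_fraction = select_fraction,
      q_threshold = q_threshold,
      seed = seed,
      boost_rounds = as.integer(boost_rounds),
      learning_rate = learning_rate,
      subsample = subsample,
      impute = impute,
      renormalize = renormalize
    ),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Deterministic sub-seed for the i-th stochastic task of a run; stays within
# 32-bit integer range.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 7919 + as.double(i) * 104729) %% 2147483647)
}
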