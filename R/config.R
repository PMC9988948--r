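#' Cohort scoring configuration
#'
#' Bundles the tunable choices of the scoring pipeline: the ten indicator
#' weights, how per-sample rates are aggregated to species level, the
#' percentile convention for adjusted-N50 scaling, PCA options for transcript
#' diversity, the reference species for relative-diversity reporting, and the
#' missing-data policy for the applicability index.
#'
#' @param weights Numeric vector of 10 non-negative weights, one per indicator
#'   in [REFQUAL_INDICATORS] order. Default all 1 (equal weighting), so the
#'   index is the plain mean of the ten indicators.
#' @param aggregation `"mean"` (unweighted mean of per-sample rates, the
#'   default) or `"pooled"` (sum counts across samples, then compute rates).
#' @param percentile `"minmax_rank"` for (rank - 1)/(n - 1) with average ranks
#'   for ties (minimum maps to 0, maximum to 1), or `"ecdf"` for rank/n.
#' @param pca `"covariance"` (PCA on mean-centered proportions, the default:
#'   columns are commensurate proportions) or `"correlation"` (unit-variance
#'   scaling before PCA).
#' @param reference_species Optional species_id used as the denominator of
#'   relative transcript diversity. `NULL` selects the most diverse species.
#' @param missing_data_policy `"complete"` (species missing any indicator are
#'   excluded from the index, the default) or `"renormalize"` (weights are
#'   renormalized over the available indicators).
#' @param shannon_s `"observed"` (evenness denominator ln S uses the species'
#'   own count of positive biotypes, the default) or `"fixed"` (use
#'   `shannon_s_fixed` for every species).
#' @param shannon_s_fixed Category count used when `shannon_s = "fixed"`;
#'   defaults to 30, the size of the canonical biotype vocabulary.
#'
#' @return An object of class `refqual_config` (a named list).
#' @export
#' @examples
#' cohort_config(weights = c(1, 1, 1, 2, 2, 2, 1, 1, 1, 1))
cohort_config <- function(weights = rep(1, 10),
                          aggregation = c("mean", "pooled"),
                          percentile = c("minmax_rank", "ecdf"),
                          pca = c("covariance", "correlation"),
                          reference_species = NULL,
                          missing_data_policy = c("complete", "renormalize"),
                          shannon_s = c("observed", "fixed"),
                          shannon_s_fixed = 30L) {
  if (!is.numeric(weights) || length(weights) != 10L || anyNA(weights) ||
      any(weights < 0) || all(weights == 0)) {
    domain_error("'weights' must be 10 non-negative numbers, not all zero")
  }
  cfg <- list(
    weights = as.numeric(weights),
    aggregation = match.arg(aggregation),
    percentile = match.arg(percentile),
    pca = match.arg(pca),
    reference_species = reference_species,
    missing_data_policy = match.arg(missing_data_policy),
    shannon_s = match.arg(shannon_s),
    shannon_s_fixed = as.integer(shannon_s_fixed)
  )
  class(cfg) <- "refqual_config"
  cfg
}

#' Read a scoring configuration from YAML
#'
#' Reads a YAML file whose keys mirror the arguments of [cohort_config()];
#' absent keys keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `refqual_config` object.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) io_error(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) parse_error("config YAML must be a mapping")
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    parse_error(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")))
  }
  do.call(cohort_config, raw)
}

#' @export
print.refqual_config <- function(x, ...) {
  cat("refqual cohort configuration\n")
  cat("  weights:            ", paste(format(x$weights), collapse = " "), "\n")
  cat("  aggregation:        ", x$aggregation, "\n")
  cat("  percentile:         ", x$percentile, "\n")
  cat("  pca:                ", x$pca, "\n")
  cat("  reference species:  ",
      if (is.null(x$reference_species)) "<most diverse>" else x$reference_species, "\n")
  cat("  missing-data policy:", x$missing_data_policy, "\n")
  cat("  Shannon S:          ",
      if (x$shannon_s == "observed") "observed biotypes" else
        sprintf("fixed (%d)", x$shannon_s_fixed), "\n")
  invisible(x)
}
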