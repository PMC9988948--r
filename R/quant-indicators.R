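#' Per-sample quantification rates
#'
#' Computes the three directional quantification indicators from a sample's
#' status-category counts. The denominator `T` is the total of all categories
#' excluding `unassigned_unmapped` (an unmapped read is a mapping failure, not
#' a quantification one):
#' `QuantRate = assigned / T`,
#' `QuantRateAbs = 1 - unassigned_no_features / T`,
#' `QuantRateAmb = 1 - unassigned_ambiguity / T`.
#' Any further failure categories count only in the denominator, so
#' `QuantRate <= QuantRateAbs + QuantRateAmb - 1`, with equality exactly when
#' no other failure category has a positive count.
#'
#' @param summary A `quant_summary` record (see [parse_quant_summary()]).
#' @return Named numeric vector `c(QuantRate=, QuantRateAbs=, QuantRateAmb=)`.
#' @export
sample_quant_rates <- function(summary) {
  counts <- summary$category_counts
  keep <- names(counts) != "unassigned_unmapped"
  total <- sum(counts[keep])
  if (total <= 0) domain_error("mapped-read denominator is zero")
  c(QuantRate = unname(counts["assigned"]) / total,
    QuantRateAbs = 1 - unname(counts["unassigned_no_features"]) / total,
    QuantRateAmb = 1 - unname(counts["unassigned_ambiguity"]) / total)
}

#' Quantification quality index
#'
#' The arithmetic mean of the three quantification rates:
#' `QQI = (QuantRate + QuantRateAbs + QuantRateAmb) / 3`.
#'
#' @param rates Numeric vector of the three rates, each in \[0, 1\].
#' @return The QQI, in \[0, 1\].
#' @export
#' @examples
#' qqi(c(0.60, 0.85, 0.75))
qqi <- function(rates) {
  if (length(rates) != 3L) domain_error("QQI requires exactly three rates")
  check_rates01(rates, "rates")
  mean(rates)
}

#' Species-level quantification indicator block
#'
#' Aggregates per-sample quantification rates to one block per species,
#' mirroring [mapping_block()]: unweighted per-sample mean by default, or
#' pooled counts.
#'
#' @param summaries List of `quant_summary` records for one species.
#' @param aggregation `"mean"` (default) or `"pooled"`.
#' @return A `quant_block`: list with `species_id`, `n_samples`, `QuantRate`,
#'   `QuantRateAbs`, `QuantRateAmb`, `QQI`, `per_sample`.
#' @export
quant_block <- function(summaries, aggregation = c("mean", "pooled")) {
  aggregation <- match.arg(aggregation)
  if (length(summaries) == 0L) return(NULL)
  per_sample <- t(vapply(summaries, sample_quant_rates, numeric(3)))
  rownames(per_sample) <- vapply(summaries, `[[`, character(1), "sample_id")
  if (aggregation == "mean") {
    agg <- colMeans(per_sample)
  } else {
    pool <- Reduce(`+`, lapply(summaries, function(s) {
      template <- c(assigned = 0, unassigned_no_features = 0,
                    unassigned_ambiguity = 0, other = 0, unassigned_unmapped = 0)
      cc <- s$category_counts
      known <- intersect(names(template), names(cc))
      template[known] <- cc[known]
      template["other"] <- sum(cc[!names(cc) %in% names(template)])
      template
    }))
    total <- sum(pool) - pool["unassigned_unmapped"]
    agg <- c(QuantRate = unname(pool["assigned"] / total),
             QuantRateAbs = unname(1 - pool["unassigned_no_features"] / total),
             QuantRateAmb = unname(1 - pool["unassigned_ambiguity"] / total))
  }
  structure(list(
    species_id = summaries[[1]]$species_id,
    n_samples = length(summaries),
    QuantRate = unname(agg["QuantRate"]),
    QuantRateAbs = unname(agg["QuantRateAbs"]),
    QuantRateAmb = unname(agg["QuantRateAmb"]),
    QQI = qqi(unname(agg)),
    per_sample = per_sample
  ), class = "quant_block")
}
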