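#' Per-sample mapping rates
#'
#' Computes the three directional mapping indicators from a sample's alignment
#' summary: `UnimapRate = unique / total`, `MapRate = 1 - unmapped / total`,
#' `MultiMapRate = 1 - multi / total`. For summaries whose dialect does not
#' report unique/multi-mapped counts (samtools-stats), the corresponding rates
#' are `NA`, never inferred. On fully partitioned counts the identity
#' `UnimapRate = MapRate + MultiMapRate - 1` holds.
#'
#' @param summary A `mapping_summary` record (see
#'   [parse_alignment_summary()]).
#' @return Named numeric vector `c(UnimapRate=, MapRate=, MultiMapRate=)`.
#' @export
sample_mapping_rates <- function(summary) {
  total <- summary$total_units
  if (is.null(total) || is.na(total) || total <= 0) {
    domain_error("total_units must be positive")
  }
  c(UnimapRate = if (is.na(summary$unique_units)) NA_real_ else
      summary$unique_units / total,
    MapRate = if (is.na(summary$unmapped_units)) NA_real_ else
      1 - summary$unmapped_units / total,
    MultiMapRate = if (is.na(summary$multi_units)) NA_real_ else
      1 - summary$multi_units / total)
}

#' Mapping quality index
#'
#' The arithmetic mean of the three mapping rates:
#' `MQI = (UnimapRate + MapRate + MultiMapRate) / 3`.
#'
#' @param rates Numeric vector of the three rates, each in \[0, 1\].
#' @return The MQI, in \[0, 1\].
#' @export
#' @examples
#' mqi(c(0.8, 0.9, 0.9))
mqi <- function(rates) {
  if (length(rates) != 3L) domain_error("MQI requires exactly three rates")
  check_rates01(rates, "rates")
  mean(rates)
}

#' Species-level mapping indicator block
#'
#' Aggregates per-sample mapping rates to one block per species. The default
#' aggregation is the unweighted mean of per-sample rates (samples are
#' typically equal-sized libraries); `"pooled"` sums the counts across
#' samples first. Rates unavailable for a sample (dialects without
#' unique/multi counts) are omitted from that rate's mean; an indicator with
#' no informative sample is `NA`. The species MQI is computed on the
#' aggregated rates and is `NA` if any component is.
#'
#' @param summaries List of `mapping_summary` records for one species.
#' @param aggregation `"mean"` (default) or `"pooled"`.
#' @return A `mapping_block`: list with `species_id`, `n_samples`,
#'   `UnimapRate`, `MapRate`, `MultiMapRate`, `MQI`, and `per_sample` (matrix
#'   of per-sample rate triples).
#' @export
mapping_block <- function(summaries, aggregation = c("mean", "pooled")) {
  aggregation <- match.arg(aggregation)
  if (length(summaries) == 0L) return(NULL)
  per_sample <- t(vapply(summaries, sample_mapping_rates, numeric(3)))
  rownames(per_sample) <- vapply(summaries, `[[`, character(1), "sample_id")
  if (aggregation == "mean") {
    agg <- colMeans(per_sample, na.rm = TRUE)
    agg[colSums(!is.na(per_sample)) == 0L] <- NA_real_
  } else {
    tot <- sum(vapply(summaries, `[[`, numeric(1), "total_units"))
    pool <- function(field) {
      v <- vapply(summaries, `[[`, numeric(1), field)
      if (anyNA(v)) NA_real_ else sum(v)
    }
    agg <- c(UnimapRate = pool("unique_units") / tot,
             MapRate = 1 - pool("unmapped_units") / tot,
             MultiMapRate = 1 - pool("multi_units") / tot)
  }
  structure(list(
    species_id = summaries[[1]]$species_id,
    n_samples = length(summaries),
    UnimapRate = unname(agg["UnimapRate"]),
    MapRate = unname(agg["MapRate"]),
    MultiMapRate = unname(agg["MultiMapRate"]),
    MQI = if (anyNA(agg)) NA_real_ else mqi(unname(agg)),
    per_sample = per_sample
  ), class = "mapping_block")
}
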