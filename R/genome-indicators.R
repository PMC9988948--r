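#' Genome-size-adjusted N50
#'
#' Divides an N50 contiguity value by the genome size, making contiguity
#' comparable across genomes of different sizes.
#'
#' @param n50 N50 length in base pairs (contig or scaffold level).
#' @param genome_size Genome size in base pairs.
#' @return The ratio `n50 / genome_size`, in (0, 1]. Vectorized.
#' @export
#' @examples
#' adjusted_n50(7154707, 1689594967)
adjusted_n50 <- function(n50, genome_size) {
  if (!is.numeric(n50) || !is.numeric(genome_size) ||
      anyNA(n50) || anyNA(genome_size) ||
      any(n50 <= 0) || any(genome_size <= 0)) {
    domain_error("n50 and genome_size must be positive")
  }
  if (any(n50 > genome_size)) domain_error("n50 exceeds genome_size")
  n50 / genome_size
}

#' Cohort percentile scaling
#'
#' Maps a cohort of values onto \[0, 1\] by rank: the minimum maps to 0, the
#' maximum to 1. The default convention is `(rank - 1) / (n - 1)` with
#' average ranks for ties, which attains both endpoints exactly; the
#' alternative `"ecdf"` convention is `rank / n`.
#'
#' @param values Numeric vector of finite values (one per species).
#' @param convention `"minmax_rank"` (default) or `"ecdf"`.
#' @return Numeric vector of the same length in \[0, 1\].
#' @export
#' @examples
#' percentile_scale(c(1, 2, 2, 3))  # 0, 0.5, 0.5, 1
percentile_scale <- function(values, convention = c("minmax_rank", "ecdf")) {
  convention <- match.arg(convention)
  if (!is.numeric(values) || length(values) == 0L || any(!is.finite(values))) {
    domain_error("percentile_scale requires finite numeric values")
  }
  n <- length(values)
  if (n == 1L) {
    warning("percentile of a single-species cohort is undefined; returning 1",
            call. = FALSE)
    return(1)
  }
  r <- rank(values, ties.method = "average")
  if (convention == "minmax_rank") (r - 1) / (n - 1) else r / n
}

#' Scaled non-spanned-gap rate
#'
#' `1 - gaps_i / max_j(gaps_j)`: the species with the most spanned gaps in the
#' cohort scores 0, a gapless assembly scores 1. An all-zero cohort (no gaps
#' anywhere) scores 1 for every species, the limit of the formula along
#' equal-quality cohorts.
#'
#' @param spanned_gaps Non-negative integer vector of spanned-gap counts, one
#'   per species.
#' @return Numeric vector in \[0, 1\].
#' @export
#' @examples
#' ungap_rate(c(125067, 204, 0))
ungap_rate <- function(spanned_gaps) {
  if (!is.numeric(spanned_gaps) || length(spanned_gaps) == 0L ||
      anyNA(spanned_gaps) || any(spanned_gaps < 0)) {
    domain_error("spanned_gaps must be non-negative counts")
  }
  m <- max(spanned_gaps)
  if (m == 0) rep(1, length(spanned_gaps)) else 1 - spanned_gaps / m
}

#' Assembly-derived indicator block for a cohort
#'
#' Computes the three assembly indicators — contig and scaffold adjusted-N50
#' percentiles and the ungap rate — cohort-relatively from per-species
#' assembly statistics.
#'
#' @param stats List of `assembly_stats` records (see
#'   [parse_assembly_stats()]).
#' @param convention Percentile convention, see [percentile_scale()].
#' @return A data.frame with columns `species_id`, `adj_n50_contig_raw`,
#'   `adj_n50_scaffold_raw`, `spanned_gaps`, `AdjN50Contig`, `AdjN50Scaffold`,
#'   `UngapRate`.
#' @export
genome_indicator_block <- function(stats, convention = "minmax_rank") {
  stats <- Filter(Negate(is.null), stats)
  if (length(stats) == 0L) domain_error("no assembly statistics supplied")
  df <- data.frame(
    species_id = vapply(stats, `[[`, character(1), "species_id"),
    stringsAsFactors = FALSE
  )
  df$adj_n50_contig_raw <- vapply(stats, function(s)
    adjusted_n50(s$contig_n50, s$genome_size), numeric(1))
  df$adj_n50_scaffold_raw <- vapply(stats, function(s)
    adjusted_n50(s$scaffold_n50, s$genome_size), numeric(1))
  df$spanned_gaps <- vapply(stats, `[[`, numeric(1), "spanned_gaps")
  df$AdjN50Contig <- suppressWarnings(
    percentile_scale(df$adj_n50_contig_raw, convention))
  df$AdjN50Scaffold <- suppressWarnings(
    percentile_scale(df$adj_n50_scaffold_raw, convention))
  df$UngapRate <- ungap_rate(df$spanned_gaps)
  rownames(df) <- NULL
  df
}
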