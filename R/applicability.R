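#' Assemble the species-by-indicator matrix
#'
#' Joins the per-module indicator blocks by species into the ten-column
#' indicator table (in canonical [REFQUAL_INDICATORS] order), plus MQI and
#' QQI. Cohort-relative indicators (the two adjusted-N50 percentiles, the
#' ungap rate and transcript diversity) are computed over the subset of
#' species with the corresponding inputs; species lacking an input get `NA`
#' for the affected cells (recorded in the completeness mask), never zeros.
#'
#' @param species_ids Character vector fixing species membership and order.
#' @param assembly List of `assembly_stats` records (may omit species).
#' @param mapping List of `mapping_block`s.
#' @param quant List of `quant_block`s.
#' @param diversity A `diversity_result`, or `NULL`.
#' @param optional_columns Optional data.frame of passthrough diagnostics
#'   keyed by `species_id` (e.g. BUSCO completeness; never folded into the
#'   index).
#' @param config A [cohort_config()].
#' @return An `indicator_matrix`: data.frame with `species_id`, the ten
#'   indicators, `MQI`, `QQI`, any passthrough columns, and a logical
#'   `completeness_mask` matrix attribute.
#' @export
assemble_indicator_matrix <- function(species_ids, assembly = list(),
                                      mapping = list(), quant = list(),
                                      diversity = NULL,
                                      optional_columns = NULL,
                                      config = cohort_config()) {
  if (length(species_ids) == 0L) domain_error("empty cohort")
  if (anyDuplicated(species_ids)) validation_error("duplicate species_id")
  df <- data.frame(species_id = species_ids, stringsAsFactors = FALSE)
  for (col in c(REFQUAL_INDICATORS, "MQI", "QQI")) df[[col]] <- NA_real_

  assembly <- Filter(Negate(is.null), assembly)
  if (length(assembly)) {
    gb <- genome_indicator_block(assembly, convention = config$percentile)
    idx <- match(gb$species_id, df$species_id)
    ok <- !is.na(idx)
    for (col in c("AdjN50Contig", "AdjN50Scaffold", "UngapRate")) {
      df[[col]][idx[ok]] <- gb[[col]][ok]
    }
  }
  fill_block <- function(df, blocks, cols, extra) {
    for (b in Filter(Negate(is.null), blocks)) {
      i <- match(b$species_id, df$species_id)
      if (is.na(i)) next
      for (col in c(cols, extra)) df[[col]][i] <- b[[col]]
    }
    df
  }
  df <- fill_block(df, mapping, c("UnimapRate", "MapRate", "MultiMapRate"), "MQI")
  df <- fill_block(df, quant, c("QuantRate", "QuantRateAbs", "QuantRateAmb"), "QQI")
  if (!is.null(diversity)) {
    idx <- match(names(diversity$transcript_diversity), df$species_id)
    ok <- !is.na(idx)
    df$TranscriptDiversity[idx[ok]] <- unname(diversity$transcript_diversity)[ok]
  }
  if (!is.null(optional_columns)) {
    idx <- match(optional_columns$species_id, df$species_id)
    for (col in setdiff(names(optional_columns), "species_id")) {
      df[[col]] <- NA_real_
      df[[col]][idx[!is.na(idx)]] <- optional_columns[[col]][!is.na(idx)]
    }
  }
  mask <- !is.na(as.matrix(df[REFQUAL_INDICATORS]))
  rownames(mask) <- df$species_id
  structure(df, completeness_mask = mask, class = c("indicator_matrix", "data.frame"))
}

#' Weighted NGS applicability index
#'
#' The weighted arithmetic mean of the ten quality indicators for each
#' species: `index_i = sum_k(w_k * indicator_ik) / sum_k(w_k)`. With the
#' default equal weights this is the plain mean of the ten indicators,
#' algebraically `(3*MQI + 3*QQI + AdjN50Contig + AdjN50Scaffold + UngapRate +
#' TranscriptDiversity) / 10`. Under the default `"complete"` missing-data
#' policy a species missing any indicator receives `NA` (excluded from
#' ranking); `"renormalize"` averages over the available indicators with
#' renormalized weights.
#'
#' @param matrix An `indicator_matrix` (or data.frame with the ten indicator
#'   columns).
#' @param weights Ten non-negative weights, not all zero.
#' @param missing_data_policy `"complete"` (default) or `"renormalize"`.
#' @return Numeric vector of indices, named by species_id.
#' @export
ngs_applicability <- function(matrix, weights = rep(1, 10),
                              missing_data_policy = c("complete", "renormalize")) {
  missing_data_policy <- match.arg(missing_data_policy)
  if (!is.numeric(weights) || length(weights) != 10L || anyNA(weights) ||
      any(weights < 0) || all(weights == 0)) {
    domain_error("weights must be 10 non-negative numbers, not all zero")
  }
  vals <- as.matrix(matrix[REFQUAL_INDICATORS])
  out <- apply(vals, 1, function(v) {
    present <- !is.na(v)
    if (missing_data_policy == "complete" && !all(present)) return(NA_real_)
    if (!any(present) || sum(weights[present]) == 0) return(NA_real_)
    sum(weights[present] * v[present]) / sum(weights[present])
  })
  setNames(unname(out), matrix$species_id)
}

#' Ranked cohort report
#'
#' Orders the cohort by descending applicability index (ties broken by
#' species_id, lexicographically) and returns the full per-species report:
#' the ten indicators, MQI, QQI, index and rank. Species without an index
#' (incomplete under the strict policy) are excluded from the ranked rows and
#' listed in the `"excluded"` attribute.
#'
#' @param matrix An `indicator_matrix`.
#' @param index Index vector from [ngs_applicability()]; recomputed with equal
#'   weights when omitted.
#' @return data.frame ordered by rank, with attribute `"excluded"`.
#' @export
rank_report <- function(matrix, index = NULL) {
  if (is.null(index)) index <- ngs_applicability(matrix)
  df <- as.data.frame(matrix)
  df$index <- unname(index[match(df$species_id, names(index))])
  excluded <- df$species_id[is.na(df$index)]
  df <- df[!is.na(df$index), , drop = FALSE]
  df <- df[order(-df$index, df$species_id), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  structure(df, excluded = excluded)
}

#' Pairwise indicator correlations
#'
#' Pearson or Spearman correlations between all pairs of numeric columns,
#' using pairwise-complete observations; pairs with fewer than 3 complete
#' observations or a constant column yield `NA`.
#'
#' @param data data.frame or matrix of numeric columns (e.g. an
#'   `indicator_matrix`).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlate_indicators <- function(data, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  df <- as.data.frame(data)
  num <- df[vapply(df, is.numeric, logical(1))]
  if (ncol(num) < 2L) domain_error("need at least two numeric columns")
  p <- ncol(num)
  out <- matrix(NA_real_, p, p, dimnames = list(names(num), names(num)))
  diag(out) <- 1
  for (i in seq_len(p - 1)) for (j in seq(i + 1, p)) {
    x <- num[[i]]; y <- num[[j]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) >= 3 && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
      out[i, j] <- out[j, i] <- cor(x[ok], y[ok], method = method)
    }
  }
  out
}

#' Compare assembly builds of the same species
#'
#' Stacks the indicator matrices of two or more builds (e.g. successive
#' reference assembly versions) into one long table for build-over-build
#' comparison of the ten indicators and the applicability index. Since the
#' index is a weighted mean, a build that improves every indicator can only
#' increase it.
#'
#' @param builds Named list of `indicator_matrix` objects, one per build.
#' @param weights Index weights (default equal).
#' @return Long data.frame with columns `build`, `species_id`, the ten
#'   indicators, `MQI`, `QQI`, `index`, and any passthrough columns; species
#'   absent from a build appear as a flagged `NA` row (`present = FALSE`).
#' @export
compare_builds <- function(builds, weights = rep(1, 10)) {
  if (!is.list(builds) || length(builds) < 2L || is.null(names(builds)) ||
      any(!nzchar(names(builds)))) {
    domain_error("builds must be a named list of >= 2 indicator matrices")
  }
  all_species <- unique(unlist(lapply(builds, `[[`, "species_id")))
  rows <- lapply(names(builds), function(bn) {
    m <- as.data.frame(builds[[bn]])
    m$index <- unname(ngs_applicability(builds[[bn]], weights))
    missing <- setdiff(all_species, m$species_id)
    if (length(missing)) {
      pad <- m[rep(NA_integer_, length(missing)), , drop = FALSE]
      pad$species_id <- missing
      m <- rbind(m, pad)
    }
    m$present <- !m$species_id %in% missing
    m$build <- bn
    m
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$species_id, match(out$build, names(builds))), ]
  rownames(out) <- NULL
  out[c("build", "species_id", setdiff(names(out), c("build", "species_id")))]
}
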