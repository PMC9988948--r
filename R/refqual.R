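#' Score a cohort of reference genomes and annotations
#'
#' The main entry point: reads every artifact referenced by a cohort manifest
#' (assembly statistics, alignment summaries, quantification summaries, GTF
#' annotations), computes the ten quality indicators, the mapping and
#' quantification quality indices (MQI, QQI), the PCA-based transcript
#' diversity, and the weighted NGS applicability index, and ranks the
#' species.
#'
#' @param manifest Path to a manifest TSV, or a `refqual_manifest` from
#'   [read_manifest()].
#' @param config A [cohort_config()].
#' @return An object of class `refqual`: list with `indicators` (the
#'   species-by-indicator matrix), `index` (named numeric), `ranking` (ranked
#'   report data.frame), `diversity` (a `diversity_result` or `NULL`),
#'   `mapping`, `quant` (per-species blocks), `assembly`, `profiles`,
#'   `manifest`, `config`, `excluded` (species without a complete index).
#' @export
#' @examples
#' \donttest{
#' dir <- file.path(tempdir(), "micro")
#' mc <- worked_micro_cohort(dir)
#' fit <- refqual(mc$manifest_path)
#' fit
#' summary(fit)
#' }
refqual <- function(manifest, config = cohort_config()) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (!inherits(manifest, "refqual_manifest")) {
    domain_error("manifest must be a path or a refqual_manifest")
  }
  if (!inherits(config, "refqual_config")) {
    domain_error("config must be a refqual_config")
  }
  species_ids <- vapply(manifest$species, `[[`, character(1), "species_id")

  assembly <- lapply(manifest$species, function(s) {
    if (is.na(s$assembly_stats_path)) return(NULL)
    parse_assembly_stats(s$assembly_stats_path, species_id = s$species_id)
  })
  mapping <- lapply(manifest$species, function(s) {
    if (length(s$mapping_summary_paths) == 0L) return(NULL)
    sums <- lapply(s$mapping_summary_paths, parse_alignment_summary,
                   species_id = s$species_id)
    mapping_block(sums, aggregation = config$aggregation)
  })
  quant <- lapply(manifest$species, function(s) {
    if (length(s$quant_summary_paths) == 0L) return(NULL)
    sums <- lapply(s$quant_summary_paths, parse_quant_summary,
                   species_id = s$species_id)
    quant_block(sums, aggregation = config$aggregation)
  })
  profiles <- lapply(manifest$species, function(s) {
    if (is.na(s$gtf_path)) return(NULL)
    asm <- assembly[[s$species_id]]
    gsize <- if (!is.null(asm)) asm$genome_size else .Machine$integer.max
    profile_gtf(s$gtf_path, genome_size = gsize, species_id = s$species_id)
  })

  diversity <- NULL
  live <- Filter(Negate(is.null), profiles)
  if (length(live) >= 2L) {
    diversity <- diversity_result(
      live,
      reference_species = config$reference_species,
      scale = config$pca,
      s_fixed = if (config$shannon_s == "fixed") config$shannon_s_fixed else NULL)
  }

  ind <- assemble_indicator_matrix(
    species_ids, assembly = assembly, mapping = mapping, quant = quant,
    diversity = diversity, optional_columns = manifest$optional_columns,
    config = config)
  index <- ngs_applicability(ind, weights = config$weights,
                             missing_data_policy = config$missing_data_policy)
  ranking <- rank_report(ind, index)

  structure(list(indicators = ind, index = index, ranking = ranking,
                 diversity = diversity, mapping = mapping, quant = quant,
                 assembly = assembly, profiles = profiles,
                 manifest = manifest, config = config,
                 excluded = attr(ranking, "excluded")),
            class = "refqual")
}

#' @export
print.refqual <- function(x, ...) {
  n <- nrow(x$indicators)
  scored <- sum(!is.na(x$index))
  cat(sprintf("refqual cohort scoring: %d species, %d scored\n", n, scored))
  if (!is.null(x$diversity)) {
    cat(sprintf("  transcript diversity PC1 explains %.1f%% of biotype-proportion variance\n",
                100 * x$diversity$variance_explained_pc1))
  }
  top <- head(x$ranking, 5L)
  cat("  top species by NGS applicability index:\n")
  for (i in seq_len(nrow(top))) {
    cat(sprintf("    %d. %-20s %.3f\n", top$rank[i], top$species_id[i], top$index[i]))
  }
  if (length(x$excluded)) {
    cat("  excluded (incomplete indicators):", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.refqual <- function(object, ...) {
  ind <- as.matrix(object$indicators[REFQUAL_INDICATORS])
  stats <- data.frame(
    indicator = REFQUAL_INDICATORS,
    n = colSums(!is.na(ind)),
    mean = colMeans(ind, na.rm = TRUE),
    min = suppressWarnings(apply(ind, 2, min, na.rm = TRUE)),
    max = suppressWarnings(apply(ind, 2, max, na.rm = TRUE)),
    row.names = NULL
  )
  out <- list(indicator_summary = stats,
              mean_mqi = mean(object$indicators$MQI, na.rm = TRUE),
              mean_qqi = mean(object$indicators$QQI, na.rm = TRUE),
              mean_index = mean(object$index, na.rm = TRUE),
              n_species = nrow(object$indicators),
              n_scored = sum(!is.na(object$index)),
              variance_explained_pc1 =
                if (is.null(object$diversity)) NA_real_
                else object$diversity$variance_explained_pc1)
  class(out) <- "summary.refqual"
  out
}

#' @export
print.summary.refqual <- function(x, ...) {
  cat(sprintf("Cohort of %d species (%d scored)\n", x$n_species, x$n_scored))
  cat(sprintf("Mean MQI %.3f, mean QQI %.3f, mean applicability index %.3f\n",
              x$mean_mqi, x$mean_qqi, x$mean_index))
  if (!is.na(x$variance_explained_pc1)) {
    cat(sprintf("PC1 variance explained: %.2f%%\n", 100 * x$variance_explained_pc1))
  }
  cat("\nPer-indicator summary:\n")
  print(x$indicator_summary, digits = 3)
  invisible(x)
}

#' @export
as.data.frame.refqual <- function(x, ...) {
  as.data.frame(x$ranking)
}

#' Plot a scored cohort
#'
#' Horizontal bar chart of the NGS applicability index, best species on top,
#' with the MQI and QQI overlaid as points.
#'
#' @param x A `refqual` object.
#' @param max_species Cap on the number of (top-ranked) species drawn.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.refqual <- function(x, max_species = 30L, ...) {
  r <- head(x$ranking, max_species)
  r <- r[rev(seq_len(nrow(r))), ]
  old <- graphics::par(mar = c(4, 9, 2, 1))
  on.exit(graphics::par(old))
  mid <- graphics::barplot(r$index, names.arg = r$species_id, horiz = TRUE,
                           las = 1, xlim = c(0, 1), col = "grey80",
                           xlab = "NGS applicability index", ...)
  graphics::points(r$MQI, mid, pch = 16, col = "steelblue")
  graphics::points(r$QQI, mid, pch = 17, col = "tomato")
  graphics::legend("bottomright", pch = c(16, 17), col = c("steelblue", "tomato"),
                   legend = c("MQI", "QQI"), bty = "n")
  invisible(x)
}
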