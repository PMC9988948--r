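#' Species-by-biotype proportion matrix
#'
#' Builds the n x p matrix of gene-biotype proportions over a cohort: columns
#' are the union of biotypes observed in any species (sorted, zero-filled for
#' species lacking a biotype) and each row is normalized by that species'
#' total gene count, so rows sum to 1.
#'
#' @param profiles List of `biotype_profile` records (see [profile_gtf()]).
#' @return A numeric matrix with species rownames and biotype colnames;
#'   species with zero genes are excluded and listed in the `"excluded"`
#'   attribute.
#' @export
biotype_proportion_matrix <- function(profiles) {
  profiles <- Filter(Negate(is.null), profiles)
  if (length(profiles) == 0L) domain_error("no biotype profiles supplied")
  n_genes <- vapply(profiles, `[[`, numeric(1), "n_genes")
  excluded <- vapply(profiles, `[[`, character(1), "species_id")[n_genes == 0]
  if (length(excluded)) {
    warning(sprintf("excluding zero-gene species: %s",
                    paste(excluded, collapse = ", ")), call. = FALSE)
    profiles <- profiles[n_genes > 0]
  }
  if (length(profiles) == 0L) domain_error("all species have zero genes")
  biotypes <- sort(unique(unlist(lapply(profiles, function(p)
    names(p$biotype_counts)))))
  mat <- t(vapply(profiles, function(p) {
    row <- setNames(numeric(length(biotypes)), biotypes)
    row[names(p$biotype_counts)] <- p$biotype_counts
    row / sum(p$biotype_counts)
  }, numeric(length(biotypes))))
  rownames(mat) <- vapply(profiles, `[[`, character(1), "species_id")
  structure(mat, excluded = excluded)
}

#' Leading principal component of the biotype proportions
#'
#' Runs PCA on the proportion matrix — mean-centered columns, covariance form
#' by default (the columns are commensurate proportions); optionally
#' correlation form — and returns the PC1 scores and the fraction of total
#' variance they explain. The sign of PC1 is mathematically arbitrary; it is
#' fixed so that scores correlate non-negatively with per-species biotype
#' richness (count of nonzero biotypes), with ties broken toward a
#' non-negative loading on the lexicographically first biotype, so that
#' richer annotations score higher.
#'
#' @param mat Proportion matrix from [biotype_proportion_matrix()] (n >= 2
#'   species, p >= 2 biotypes).
#' @param scale `"covariance"` (default) or `"correlation"`.
#' @return List with `pc1_scores` (named by species), `variance_explained_pc1`
#'   and `loadings` (named by biotype).
#' @export
pca_pc1 <- function(mat, scale = c("covariance", "correlation")) {
  scale <- match.arg(scale)
  if (!is.matrix(mat) || nrow(mat) < 2L || ncol(mat) < 2L) {
    domain_error("PCA requires at least 2 species and 2 biotypes")
  }
  centered <- base::scale(mat, center = TRUE, scale = FALSE)
  if (all(abs(centered) < 1e-15)) {
    domain_error("degenerate cohort: zero total variance across species")
  }
  if (scale == "correlation") {
    sds <- apply(mat, 2, stats::sd)
    keep <- sds > 0
    fit <- prcomp(mat[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
    loadings <- setNames(numeric(ncol(mat)), colnames(mat))
    loadings[keep] <- fit$rotation[, 1]
  } else {
    fit <- prcomp(mat, center = TRUE, scale. = FALSE)
    loadings <- setNames(fit$rotation[, 1], colnames(mat))
  }
  scores <- fit$x[, 1]
  ve <- fit$sdev[1]^2 / sum(fit$sdev^2)

  richness <- rowSums(mat > 0)
  r <- if (stats::sd(richness) > 0 && stats::sd(scores) > 0) {
    cor(scores, richness)
  } else NA_real_
  flip <- if (!is.na(r) && r != 0) {
    r < 0
  } else {
    lead <- loadings[order(names(loadings))]
    lead <- lead[lead != 0]
    length(lead) > 0 && lead[1] < 0
  }
  if (flip) {
    scores <- -scores
    loadings <- -loadings
  }
  list(pc1_scores = setNames(scores, rownames(mat)),
       variance_explained_pc1 = unname(ve),
       loadings = loadings)
}

#' Min-max-scaled transcript diversity
#'
#' Affinely rescales the PC1 scores to \[0, 1\]:
#' `(X - min(X)) / (max(X) - min(X))`. The most diverse species in the cohort
#' scores 1, the least diverse 0; the scaling is invariant to affine
#' transformations of the scores.
#'
#' @param pc1_scores Numeric vector of PC1 scores (>= 2 species).
#' @return Numeric vector in \[0, 1\], names preserved.
#' @export
transcript_diversity <- function(pc1_scores) {
  if (!is.numeric(pc1_scores) || length(pc1_scores) < 2L ||
      any(!is.finite(pc1_scores))) {
    domain_error("transcript_diversity requires >= 2 finite scores")
  }
  rng <- range(pc1_scores)
  if (rng[1] == rng[2]) {
    domain_error("degenerate cohort: constant PC1 scores")
  }
  (pc1_scores - rng[1]) / (rng[2] - rng[1])
}

#' Shannon's equitability of a biotype-proportion vector
#'
#' Evenness of the biotype composition: Shannon entropy
#' `H = -sum(p_i * ln p_i)` over positive proportions, divided by `ln(S)`
#' where `S` is the number of positive-proportion biotypes (or a fixed
#' category count via `s_fixed`). A single-biotype annotation has
#' equitability 0 by convention; a perfectly even one has 1.
#'
#' @param proportions Non-negative numeric vector summing to 1.
#' @param s_fixed Optional fixed `S` (e.g. 30, the full vocabulary size)
#'   replacing the observed positive-biotype count.
#' @return Equitability in \[0, 1\].
#' @export
#' @examples
#' shannon_equitability(c(0.5, 0.25, 0.25))
shannon_equitability <- function(proportions, s_fixed = NULL) {
  if (!is.numeric(proportions) || anyNA(proportions) || any(proportions < 0)) {
    domain_error("proportions must be non-negative")
  }
  if (abs(sum(proportions) - 1) > 1e-6) {
    domain_error("proportions must sum to 1")
  }
  p <- proportions[proportions > 0]
  if (length(p) == 0L) domain_error("at least one positive proportion required")
  s <- if (is.null(s_fixed)) length(p) else s_fixed
  if (s <= 1) return(0)
  h <- -sum(p * log(p))
  h / log(s)
}

#' Correlation of each biotype's proportion with transcript diversity
#'
#' Pearson correlation of every biotype column of the proportion matrix with
#' the per-species diversity vector, identifying which biotypes drive the
#' diversity axis (e.g. lncRNA content in well-curated annotations).
#'
#' @param mat Proportion matrix from [biotype_proportion_matrix()].
#' @param diversity Numeric vector, one value per species (n >= 3).
#' @return data.frame with columns `biotype` and `correlation` (`NA` for
#'   constant columns, where the correlation is undefined).
#' @export
biotype_diversity_correlation <- function(mat, diversity) {
  if (nrow(mat) < 3L || length(diversity) != nrow(mat)) {
    domain_error("need >= 3 species and one diversity value per species")
  }
  corr <- apply(mat, 2, function(col) {
    if (stats::sd(col) == 0 || stats::sd(diversity) == 0) NA_real_
    else cor(col, diversity)
  })
  data.frame(biotype = colnames(mat), correlation = unname(corr),
             stringsAsFactors = FALSE)
}

#' Cohort transcript-diversity result
#'
#' Convenience wrapper running [biotype_proportion_matrix()], [pca_pc1()],
#' [transcript_diversity()] and per-species [shannon_equitability()], plus
#' diversity relative to a reference species.
#'
#' @param profiles List of `biotype_profile` records.
#' @param reference_species species_id whose diversity anchors the relative
#'   scale; default the cohort's most diverse species.
#' @param scale PCA form, see [pca_pc1()].
#' @param s_fixed Optional fixed Shannon `S`, see [shannon_equitability()].
#' @return A `diversity_result`: list with `matrix`, `pc1_scores`,
#'   `variance_explained_pc1`, `loadings`, `transcript_diversity`,
#'   `shannon_equitability`, `relative_to_reference`, `reference_species`.
#' @export
diversity_result <- function(profiles, reference_species = NULL,
                             scale = "covariance", s_fixed = NULL) {
  mat <- biotype_proportion_matrix(profiles)
  pca <- pca_pc1(mat, scale)
  div <- transcript_diversity(pca$pc1_scores)
  eq <- apply(mat, 1, shannon_equitability, s_fixed = s_fixed)
  ref <- reference_species %||% names(div)[which.max(div)]
  if (!ref %in% names(div)) {
    domain_error(sprintf("reference species '%s' not in cohort", ref))
  }
  rel <- if (div[ref] > 0) div / div[ref] else rep(NA_real_, length(div))
  structure(list(matrix = mat, pc1_scores = pca$pc1_scores,
                 variance_explained_pc1 = pca$variance_explained_pc1,
                 loadings = pca$loadings, transcript_diversity = div,
                 shannon_equitability = eq,
                 relative_to_reference = rel, reference_species = ref),
            class = "diversity_result")
}
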