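test_that("biotype_proportion_matrix unions biotypes and normalizes rows", {
  a <- bp("A", c(protein_coding = 2L, lncRNA = 1L))
  b <- bp("B", c(protein_coding = 1L))
  m <- biotype_proportion_matrix(list(a, b))
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(m["A", ], c(lncRNA = 1 / 3, protein_coding = 2 / 3))
  expect_equal(m["B", ], c(lncRNA = 0, protein_coding = 1))

  m2 <- biotype_proportion_matrix(list(a, a))
  expect_equal(unname(m2[1, ]), unname(m2[2, ]))

  set.seed(47)
  profs <- lapply(1:8, function(i) {
    k <- sample(2:6, 1)
    bp(paste0("sp", i), setNames(sample(1:50, k), sample(letters, k)))
  })
  m3 <- biotype_proportion_matrix(profs)
  expect_equal(unname(rowSums(m3)), rep(1, 8), tolerance = 1e-12)
  expect_true(all(m3 >= 0 & m3 <= 1))
})

test_that("pca_pc1 matches a dense symmetric eigendecomposition oracle", {
  set.seed(53)
  for (rep in 1:10) {
    n <- sample(3:10, 1); p <- sample(3:6, 1)
    m <- matrix(rgamma(n * p, 1), n, p)
    m <- m / rowSums(m)
    colnames(m) <- paste0("bt", seq_len(p))
    rownames(m) <- paste0("sp", seq_len(n))
    got <- pca_pc1(m)
    cm <- scale(m, center = TRUE, scale = FALSE)
    e <- eigen(stats::cov(cm), symmetric = TRUE)
    scores <- unname(drop(cm %*% e$vectors[, 1]))
    s <- sign(sum(scores * got$pc1_scores))
    expect_equal(unname(got$pc1_scores), s * scores, tolerance = 1e-8)
    expect_equal(got$variance_explained_pc1, e$values[1] / sum(e$values),
                 tolerance = 1e-8)
  }
})

test_that("pca_pc1 degenerate geometries behave as documented", {
  two <- rbind(a = c(0.2, 0.3, 0.5), b = c(0.6, 0.1, 0.3))
  colnames(two) <- c("x", "y", "z")
  expect_equal(pca_pc1(two)$variance_explained_pc1, 1, tolerance = 1e-12)

  onecol <- cbind(v = c(0.1, 0.5, 0.9), w = 0.3)
  rownames(onecol) <- paste0("s", 1:3)
  r <- pca_pc1(onecol)
  expect_equal(r$variance_explained_pc1, 1, tolerance = 1e-12)
  expect_equal(abs(unname(r$loadings["v"])), 1, tolerance = 1e-12)

  flat <- matrix(0.5, 3, 2, dimnames = list(paste0("s", 1:3), c("a", "b")))
  expect_error(pca_pc1(flat), class = "refqual_domain_error")
})

test_that("PC1 orientation makes richer annotations score higher", {
  m <- rbind(rich = c(0.5, 0.3, 0.2), mid = c(0.7, 0.3, 0), poor = c(1, 0, 0))
  colnames(m) <- c("protein_coding", "lncRNA", "miRNA")
  scores <- pca_pc1(m)$pc1_scores
  expect_gt(scores["rich"], scores["poor"])
  # permuting species rows permutes outputs; permuting columns keeps scores
  perm <- c(3, 1, 2)
  expect_equal(unname(pca_pc1(m[perm, ])$pc1_scores), unname(scores[perm]),
               tolerance = 1e-10)
  expect_equal(unname(pca_pc1(m[, c(2, 3, 1)])$pc1_scores), unname(scores),
               tolerance = 1e-10)
})

test_that("transcript_diversity is the affine min-max map", {
  expect_equal(transcript_diversity(c(-1, 0, 3)), c(0, 0.25, 1))
  set.seed(59)
  x <- rnorm(20)
  d <- transcript_diversity(x)
  expect_equal(d[which.max(x)], 1)
  expect_equal(d[which.min(x)], 0)
  a <- runif(1, 0.5, 3); b <- rnorm(1)
  expect_equal(transcript_diversity(a * x + b), d, tolerance = 1e-12)
  expect_error(transcript_diversity(rep(2, 5)), class = "refqual_domain_error")
  # adding an all-zero biotype column leaves diversity unchanged
  m <- matrix(rgamma(12, 1), 4, 3); m <- m / rowSums(m)
  dimnames(m) <- list(paste0("s", 1:4), paste0("b", 1:3))
  m0 <- cbind(m, azero = 0)
  expect_equal(unname(transcript_diversity(pca_pc1(m0)$pc1_scores)),
               unname(transcript_diversity(pca_pc1(m)$pc1_scores)),
               tolerance = 1e-10)
})

test_that("shannon_equitability matches the entropy formula", {
  expect_equal(shannon_equitability(rep(0.25, 4)), 1)
  expect_equal(shannon_equitability(c(1, 0, 0)), 0)
  expect_equal(shannon_equitability(c(0.5, 0.25, 0.25)), 0.946395,
               tolerance = 1e-6 / 0.946395)
  expect_error(shannon_equitability(c(-0.5, 1.5)), class = "refqual_domain_error")
  # cross-check against vegan's Shannon H on random compositions
  skip_if_not_installed("vegan")
  set.seed(61)
  for (rep in 1:10) {
    p <- rgamma(6, 1); p <- p / sum(p)
    expect_equal(shannon_equitability(p),
                 vegan::diversity(p, index = "shannon") / log(sum(p > 0)),
                 tolerance = 1e-10)
  }
  expect_equal(shannon_equitability(c(0.5, 0.5), s_fixed = 4),
               log(2) / log(4), tolerance = 1e-12)
})

test_that("biotype_diversity_correlation matches the textbook formula", {
  set.seed(67)
  m <- matrix(rgamma(24, 1), 6, 4); m <- m / rowSums(m)
  colnames(m) <- paste0("bt", 1:4)
  rownames(m) <- paste0("sp", 1:6)
  d <- runif(6)
  tab <- biotype_diversity_correlation(m, d)
  for (j in 1:4) {
    x <- m[, j]
    oracle <- sum((x - mean(x)) * (d - mean(d))) /
      sqrt(sum((x - mean(x))^2) * sum((d - mean(d))^2))
    expect_equal(tab$correlation[j], oracle, tolerance = 1e-10)
  }
  tab2 <- biotype_diversity_correlation(cbind(m, same = d, anti = -d, const = 0), d)
  expect_equal(tab2$correlation[tab2$biotype == "same"], 1, tolerance = 1e-12)
  expect_equal(tab2$correlation[tab2$biotype == "anti"], -1, tolerance = 1e-12)
  expect_true(is.na(tab2$correlation[tab2$biotype == "const"]))
  expect_error(biotype_diversity_correlation(m[1:2, ], d[1:2]),
               class = "refqual_domain_error")
})

test_that("diversity_result reports diversity relative to a reference", {
  profs <- list(bp("rich", c(protein_coding = 5L, lncRNA = 3L, miRNA = 2L)),
                bp("mid", c(protein_coding = 7L, lncRNA = 3L)),
                bp("poor", c(protein_coding = 10L)))
  r <- diversity_result(profs)
  expect_equal(r$reference_species, "rich")
  expect_equal(unname(r$relative_to_reference["rich"]), 1)
  expect_true(all(r$transcript_diversity >= 0 & r$transcript_diversity <= 1))
  r2 <- diversity_result(profs, reference_species = "mid")
  expect_equal(unname(r2$relative_to_reference["rich"]),
               unname(r2$transcript_diversity["rich"] / r2$transcript_diversity["mid"]))
})
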