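make_full_matrix <- function(n = 3, seed = 71) {
  set.seed(seed)
  df <- data.frame(species_id = sprintf("sp%02d", seq_len(n)),
                   stringsAsFactors = FALSE)
  for (col in REFQUAL_INDICATORS) df[[col]] <- runif(n)
  df$MQI <- rowMeans(df[c("UnimapRate", "MapRate", "MultiMapRate")])
  df$QQI <- rowMeans(df[c("QuantRate", "QuantRateAbs", "QuantRateAmb")])
  df
}

test_that("assemble_indicator_matrix joins blocks and masks missing cells", {
  stats <- list(asm("a", 1e6, 2e5, 5e5, 0), asm("b", 2e6, 1e5, 4e5, 100),
                asm("c", 1e6, 1e4, 5e4, 400))
  mb <- lapply(c(a = "a", b = "b", c = "c"), function(s)
    mapping_block(list(ms(100, 80, 10, 10, species_id = s))))
  qb <- lapply(c(a = "a", b = "b", c = "c"), function(s)
    quant_block(list(qs(c(assigned = 60, unassigned_ambiguity = 25,
                          unassigned_no_features = 15), species_id = s))))
  div <- diversity_result(list(
    bp("a", c(protein_coding = 5L, lncRNA = 3L, miRNA = 2L)),
    bp("b", c(protein_coding = 7L, lncRNA = 3L)),
    bp("c", c(protein_coding = 10L))))
  im <- assemble_indicator_matrix(c("a", "b", "c"), stats, mb, qb, div)
  mask <- attr(im, "completeness_mask")
  expect_true(all(mask))
  expect_equal(im$AdjN50Contig, c(1, 0.5, 0))
  expect_equal(im$MQI, rep(mqi(c(0.8, 0.9, 0.9)), 3))

  # one species lacking an annotation: only its diversity cell is masked
  div2 <- diversity_result(list(
    bp("a", c(protein_coding = 5L, lncRNA = 3L, miRNA = 2L)),
    bp("c", c(protein_coding = 10L))))
  im2 <- assemble_indicator_matrix(c("a", "b", "c"), stats, mb, qb, div2)
  mask2 <- attr(im2, "completeness_mask")
  expect_false(mask2["b", "TranscriptDiversity"])
  expect_equal(sum(!mask2), 1L)

  # join is order-independent
  im3 <- assemble_indicator_matrix(c("a", "b", "c"), rev(stats), rev(mb),
                                   rev(qb), div)
  expect_equal(as.data.frame(im3), as.data.frame(im), ignore_attr = TRUE)
})

test_that("ngs_applicability is the weighted mean with both missing policies", {
  df <- make_full_matrix(1)
  df[REFQUAL_INDICATORS] <- as.list(rep(1, 10))
  expect_equal(unname(ngs_applicability(df)), 1)
  df[REFQUAL_INDICATORS] <- as.list(c(rep(1, 5), rep(0, 5)))
  expect_equal(unname(ngs_applicability(df)), 0.5)

  set.seed(73)
  df2 <- make_full_matrix(6)
  w <- runif(10, 0.1, 3)
  got <- ngs_applicability(df2, w)
  oracle <- apply(as.matrix(df2[REFQUAL_INDICATORS]), 1,
                  function(v) sum(w * v) / sum(w))
  expect_equal(unname(got), unname(oracle), tolerance = 1e-12)
  # weight scale invariance
  expect_equal(ngs_applicability(df2, 7.3 * w), got, tolerance = 1e-12)

  df2$UngapRate[2] <- NA
  strict <- ngs_applicability(df2, w)
  expect_true(is.na(strict[2]) && !anyNA(strict[-2]))
  renorm <- ngs_applicability(df2, w, missing_data_policy = "renormalize")
  keep <- REFQUAL_INDICATORS != "UngapRate"
  expect_equal(unname(renorm[2]),
               sum(w[keep] * unlist(df2[2, REFQUAL_INDICATORS][keep])) / sum(w[keep]),
               tolerance = 1e-12)
})

test_that("equal-weight index equals (3 MQI + 3 QQI + 4 remaining)/10", {
  df <- make_full_matrix(10, seed = 79)
  idx <- ngs_applicability(df)
  identity <- (3 * df$MQI + 3 * df$QQI + df$AdjN50Contig + df$AdjN50Scaffold +
                 df$UngapRate + df$TranscriptDiversity) / 10
  expect_equal(unname(idx), identity, tolerance = 1e-12)
})

test_that("improving one indicator never lowers the index", {
  set.seed(83)
  df <- make_full_matrix(5)
  w <- runif(10, 0, 2); w[1] <- 1
  base <- ngs_applicability(df, w)
  for (col in REFQUAL_INDICATORS) {
    df2 <- df
    df2[[col]] <- pmin(df2[[col]] + 0.1, 1)
    expect_true(all(ngs_applicability(df2, w) >= base - 1e-12))
  }
})

test_that("rank_report orders by index with lexicographic tie-break", {
  df <- make_full_matrix(3)
  r <- rank_report(df, setNames(c(0.9, 0.5, 0.7), df$species_id))
  expect_equal(r$species_id, c("sp01", "sp03", "sp02"))
  expect_equal(r$rank, 1:3)

  tied <- setNames(c(0.5, 0.5, 0.9), c("zeta", "alpha", "mid"))
  df$species_id <- names(tied)
  r2 <- rank_report(df, tied)
  expect_equal(r2$species_id, c("mid", "alpha", "zeta"))

  with_na <- setNames(c(0.9, NA, 0.7), df$species_id)
  r3 <- rank_report(df, with_na)
  expect_equal(nrow(r3), 2L)
  expect_equal(attr(r3, "excluded"), df$species_id[2])
})

test_that("correlate_indicators builds a symmetric pairwise table", {
  set.seed(89)
  d <- data.frame(x = rnorm(10))
  d$self <- d$x
  d$anti <- -rank(d$x)
  d$noise <- rnorm(10)
  d$const <- 1
  cc <- correlate_indicators(d)
  expect_equal(cc["x", "self"], 1, tolerance = 1e-12)
  expect_equal(cc, t(cc))
  expect_true(all(diag(cc) == 1))
  expect_true(is.na(cc["x", "const"]))
  cs <- correlate_indicators(d, method = "spearman")
  expect_equal(cs["x", "anti"], -1, tolerance = 1e-12)
  oracle <- cor(d$x, d$noise)
  expect_equal(cc["x", "noise"], oracle, tolerance = 1e-10)
})

test_that("compare_builds stacks builds and preserves dominance", {
  a <- make_full_matrix(3, seed = 97)
  b <- a
  b[REFQUAL_INDICATORS] <- lapply(a[REFQUAL_INDICATORS],
                                  function(v) pmin(v + 0.05, 1))
  same <- compare_builds(list(v1 = a, v2 = a))
  expect_equal(same$index[same$build == "v1"], same$index[same$build == "v2"])

  dom <- compare_builds(list(v1 = a, v2 = b))
  i1 <- dom$index[dom$build == "v1"]; i2 <- dom$index[dom$build == "v2"]
  expect_true(all(i2 >= i1))

  # synthetic 3-build gradient: strictly increasing indices
  c3 <- b
  c3[REFQUAL_INDICATORS] <- lapply(b[REFQUAL_INDICATORS],
                                   function(v) pmin(v + 0.05, 1))
  grad <- compare_builds(list(v1 = a, v2 = b, v3 = c3))
  for (sp in a$species_id) {
    idx <- grad$index[grad$species_id == sp]
    expect_true(all(diff(idx) > 0))
  }

  # species absent from one build appears flagged
  miss <- compare_builds(list(v1 = a, v2 = a[1:2, ]))
  row <- miss[miss$build == "v2" & miss$species_id == a$species_id[3], ]
  expect_false(row$present)
  expect_true(is.na(row$index))
})
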