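test_that("read_manifest loads a well-formed cohort and resolves paths", {
  dir <- tempfile("man")
  dir.create(dir)
  asm_path <- file.path(dir, "a.tsv")
  writeLines(c("genome_size\tcontig_n50\tscaffold_n50\tspanned_gaps",
               "1000000\t100000\t200000\t10"), asm_path)
  writeLines(c("species_id\tdisplay_name\tassembly_stats\tgtf\tmapping_summaries\tquant_summaries\tbusco_completeness",
               "human\tHuman\ta.tsv\t\t\t\t0.99",
               "mouse\tMouse\ta.tsv\t\t\t\t0.98",
               "frog\tFrog\t\t\t\t\t"),
             file.path(dir, "manifest.tsv"))
  m <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_s3_class(m, "refqual_manifest")
  expect_length(m$species, 3L)
  expect_equal(m$species$human$assembly_stats_path, normalizePath(asm_path))
  expect_true("annotation" %in% m$species$human$missing)
  expect_true("assembly_stats" %in% m$species$frog$missing)
  # optional column numeric, absent recorded as NA not zero
  expect_equal(m$optional_columns$busco_completeness, c(0.99, 0.98, NA))
  expect_output(print(m), "3 species")
})

test_that("read_manifest rejects duplicates and malformed headers", {
  p <- write_tmp(c("species_id\tdisplay_name\tassembly_stats\tgtf\tmapping_summaries\tquant_summaries",
                   "mouse\tM\t\t\t\t", "mouse\tM2\t\t\t\t"))
  expect_error(read_manifest(p), "duplicate species_id.*mouse")
  p2 <- write_tmp(c("species\tname", "a\tb"))
  expect_error(read_manifest(p2), "lacks column")
})

test_that("parse_assembly_stats reads TSV, rejects invariant violations, flags NA", {
  p <- write_tmp(c("genome_size\tcontig_n50\tscaffold_n50\tspanned_gaps",
                   "1,689,594,967\t7,154,707\t80,000,000\t204"))
  a <- parse_assembly_stats(p, species_id = "human")
  expect_equal(a$genome_size, 1689594967)
  expect_equal(a$contig_n50, 7154707)
  expect_equal(a$spanned_gaps, 204)

  p_bad <- write_tmp(c("genome_size\tcontig_n50\tscaffold_n50\tspanned_gaps",
                       "1000\t2000\t500\t0"))
  expect_error(parse_assembly_stats(p_bad), "contig_n50 exceeds")

  p_na <- write_tmp(c("genome_size\tcontig_n50\tscaffold_n50\tspanned_gaps",
                      "1000\t100\t500\tNA"))
  expect_warning(res <- parse_assembly_stats(p_na), "assembly-stats-missing")
  expect_null(res)

  p_miss <- write_tmp(c("genome_size\tcontig_n50", "1000\t100"))
  expect_error(parse_assembly_stats(p_miss), "missing field")
})

test_that("parse_assembly_stats reads the ENA XML dialect", {
  p <- write_tmp(c(
    "<ASSEMBLY>", "<ASSEMBLY_ATTRIBUTES>",
    "<ASSEMBLY_ATTRIBUTE><TAG>total-length</TAG><VALUE>1000000</VALUE></ASSEMBLY_ATTRIBUTE>",
    "<ASSEMBLY_ATTRIBUTE><TAG>contig-n50</TAG><VALUE>50000</VALUE></ASSEMBLY_ATTRIBUTE>",
    "<ASSEMBLY_ATTRIBUTE><TAG>scaffold-n50</TAG><VALUE>200000</VALUE></ASSEMBLY_ATTRIBUTE>",
    "<ASSEMBLY_ATTRIBUTE><TAG>spanned-gaps</TAG><VALUE>42</VALUE></ASSEMBLY_ATTRIBUTE>",
    "</ASSEMBLY_ATTRIBUTES>", "</ASSEMBLY>"), ".xml")
  a <- parse_assembly_stats(p, species_id = "x")
  expect_equal(a$contig_n50, 50000)
  expect_equal(a$spanned_gaps, 42)
})

test_that("parse_alignment_summary handles the paired hisat2 dialect", {
  p <- write_tmp(c(
    "100000 reads; of these:",
    "  100000 (100.00%) were paired; of these:",
    "    5000 (5.00%) aligned concordantly 0 times",
    "    85000 (85.00%) aligned concordantly exactly 1 time",
    "    10000 (10.00%) aligned concordantly >1 times",
    "95.00% overall alignment rate"))
  s <- parse_alignment_summary(p, species_id = "sp")
  expect_equal(s$total_units, 100000)
  expect_equal(s$unique_units, 85000)
  expect_equal(s$multi_units, 10000)
  expect_equal(s$unmapped_units, 5000)
  expect_equal(s$unit, "pair")
})

test_that("degenerate all-unique summary and error contracts", {
  p <- write_tmp(c(
    "500 reads; of these:",
    "  500 (100.00%) were paired; of these:",
    "    0 (0.00%) aligned concordantly 0 times",
    "    500 (100.00%) aligned concordantly exactly 1 time",
    "    0 (0.00%) aligned concordantly >1 times",
    "100.00% overall alignment rate"))
  s <- parse_alignment_summary(p)
  expect_equal(s$unique_units, s$total_units)
  expect_equal(s$multi_units + s$unmapped_units, 0)

  trunc <- write_tmp(c("100000 reads; of these:",
                       "  100000 (100.00%) were paired; of these:"))
  expect_error(parse_alignment_summary(trunc), "truncated")
  junk <- write_tmp(c("hello", "world"))
  expect_error(parse_alignment_summary(junk), "supported: hisat2, samtools_stats")

  bad <- write_tmp(c(
    "100 reads; of these:",
    "  100 (100.00%) were paired; of these:",
    "    10 (10.00%) aligned concordantly 0 times",
    "    80 (80.00%) aligned concordantly exactly 1 time",
    "    30 (30.00%) aligned concordantly >1 times"))
  expect_error(parse_alignment_summary(bad), "residual")
})

test_that("samtools-stats dialect records multi/unique as missing", {
  p <- write_tmp(c("SN\traw total sequences:\t200000",
                   "SN\treads mapped:\t190000",
                   "SN\treads unmapped:\t10000"))
  s <- parse_alignment_summary(p)
  expect_equal(s$total_units, 200000)
  expect_equal(s$unmapped_units, 10000)
  expect_true(is.na(s$unique_units) && is.na(s$multi_units))
  r <- sample_mapping_rates(s)
  expect_equal(unname(r["MapRate"]), 0.95)
  expect_true(is.na(r["UnimapRate"]) && is.na(r["MultiMapRate"]))
})

test_that("parse_quant_summary normalizes categories and validates counts", {
  p <- write_tmp(c("Status\tsample.bam", "Assigned\t60",
                   "Unassigned_Ambiguity\t25", "Unassigned_NoFeatures\t15"))
  q <- parse_quant_summary(p, species_id = "sp")
  expect_setequal(names(q$category_counts),
                  c("assigned", "unassigned_ambiguity", "unassigned_no_features"))
  expect_equal(unname(q$category_counts["assigned"]), 60)
  expect_equal(q$sample_id, "sample")

  p2 <- write_tmp(c("Status\ts.bam", "Assigned\t60", "Unassigned_Ambiguity\t25",
                    "Unassigned_NoFeatures\t15", "Unassigned_Unmapped\t40",
                    "Unassigned_Foo\t5"))
  q2 <- parse_quant_summary(p2)
  expect_true(all(c("unassigned_unmapped", "unassigned_foo") %in%
                    names(q2$category_counts)))
  # unknown category counts in the denominator, unmapped does not
  r <- sample_quant_rates(q2)
  expect_equal(unname(r["QuantRate"]), 60 / 105)

  neg <- write_tmp(c("Status\ts", "Assigned\t-1", "Unassigned_Ambiguity\t0",
                     "Unassigned_NoFeatures\t0"))
  expect_error(parse_quant_summary(neg), "negative")
  empty <- write_tmp("Status\ts")
  expect_error(parse_quant_summary(empty), "empty")
})

test_that("indicator table round-trips with empty cells for missing values", {
  df <- data.frame(species_id = c("a", "b", "c"))
  for (col in REFQUAL_INDICATORS) df[[col]] <- runif(3)
  df$MQI <- runif(3); df$QQI <- runif(3)
  df$index <- runif(3); df$rank <- 1:3
  df$TranscriptDiversity[2] <- NA
  path <- tempfile(fileext = ".tsv")
  write_indicator_table(df, path)
  lines <- readLines(path)
  expect_length(lines, 4L)
  expect_true(grepl("\t\t", lines[3]))  # empty cell, not zero
  back <- read_indicator_table(path)
  expect_equal(back$species_id, df$species_id)
  for (col in c(REFQUAL_INDICATORS, "MQI", "QQI", "index")) {
    expect_equal(back[[col]], df[[col]], tolerance = 1e-8)
  }
  expect_true(is.na(back$TranscriptDiversity[2]))
})
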