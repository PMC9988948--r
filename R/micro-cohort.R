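#' Worked three-species micro cohort with golden expectations
#'
#' Writes a fixed, fully deterministic three-species cohort ("alpha",
#' "bravo", "charlie" — a high-, mid- and low-quality reference in every
#' dimension) to disk in exactly the dialects the parsers consume, together
#' with its golden expected indicator table. Every indicator, MQI, QQI,
#' transcript diversity and applicability index in the golden table was
#' computed by hand from the defining formulas (the PCA diversity from an
#' independent eigendecomposition of the 3 x 3 proportion matrix) and frozen
#' here, so a pipeline run over the fixture can be checked end to end.
#'
#' @param dir Directory to write the fixture into (created if needed).
#' @return List with `dir`, `manifest_path`, and `golden` (data.frame of
#'   species_id, the ten indicators, MQI, QQI, index — the hand-computed
#'   expectations).
#' @export
worked_micro_cohort <- function(dir = tempfile("micro_cohort")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- c("alpha", "bravo", "charlie")
  for (s in sp) dir.create(file.path(dir, s), showWarnings = FALSE)

  # Assembly: genome size, contig N50, scaffold N50, spanned gaps.
  asm <- list(alpha = c(1e6, 200000, 500000, 0),
              bravo = c(2e6, 100000, 400000, 100),
              charlie = c(1e6, 10000, 50000, 400))
  for (s in sp) {
    writeLines(c("genome_size\tcontig_n50\tscaffold_n50\tspanned_gaps",
                 paste(format(asm[[s]], scientific = FALSE, trim = TRUE),
                       collapse = "\t")),
               file.path(dir, s, "assembly.tsv"))
  }

  # Mapping: two samples each, totals of 1000 (unique, multi, unmapped).
  mapping <- list(
    alpha = list(c(900, 60, 40), c(860, 80, 60)),
    bravo = list(c(700, 150, 150), c(660, 170, 170)),
    charlie = list(c(500, 200, 300), c(460, 240, 300)))
  for (s in sp) for (k in 1:2) {
    m <- mapping[[s]][[k]]
    write_hisat2_summary(file.path(dir, s, sprintf("sample_%d.hisat2.txt", k)),
                         total = 1000, unique = m[1], multi = m[2], unmapped = m[3])
  }

  # Quantification: (assigned, no_features, ambiguity, secondary[, unmapped]).
  quant <- list(
    alpha = list(c(800, 60, 120, 20, 0), c(760, 80, 140, 20, 100)),
    bravo = list(c(600, 230, 150, 20, 0), c(560, 250, 170, 20, 0)),
    charlie = list(c(400, 480, 100, 20, 0), c(360, 500, 120, 20, 0)))
  for (s in sp) for (k in 1:2) {
    q <- quant[[s]][[k]]
    writeLines(c(sprintf("Status\tsample_%d.bam", k),
                 sprintf("Assigned\t%d", q[1]),
                 sprintf("Unassigned_Unmapped\t%d", q[5]),
                 sprintf("Unassigned_NoFeatures\t%d", q[2]),
                 sprintf("Unassigned_Ambiguity\t%d", q[3]),
                 sprintf("Unassigned_Secondary\t%d", q[4])),
               file.path(dir, s, sprintf("sample_%d.fc.summary", k)))
  }

  # Annotations: fixed biotype counts; 100 genes of 500 bp each, 500 bp apart.
  biotypes <- list(
    alpha = rep(c("protein_coding", "lncRNA", "miRNA"), c(50, 30, 20)),
    bravo = rep(c("protein_coding", "lncRNA"), c(70, 30)),
    charlie = rep("protein_coding", 100))
  for (s in sp) {
    bts <- biotypes[[s]]
    lines <- character(0)
    for (i in seq_along(bts)) {
      start <- (i - 1) * 1000 + 1
      end <- start + 499
      attr_g <- sprintf('gene_id "%s_g%03d"; gene_biotype "%s";', s, i, bts[i])
      lines <- c(lines,
                 sprintf("chr1\tmicro\tgene\t%d\t%d\t.\t+\t.\t%s", start, end, attr_g),
                 sprintf("chr1\tmicro\texon\t%d\t%d\t.\t+\t.\t%s transcript_id \"%s_g%03d.t1\";",
                         start, end, attr_g, s, i))
    }
    writeLines(lines, file.path(dir, s, "annotation.gtf"))
  }

  manifest_path <- file.path(dir, "manifest.tsv")
  writeLines(c(
    paste("species_id", "display_name", "assembly_stats", "gtf",
          "mapping_summaries", "quant_summaries", sep = "\t"),
    vapply(sp, function(s) {
      paste(s, s, file.path(s, "assembly.tsv"), file.path(s, "annotation.gtf"),
            paste(file.path(s, sprintf("sample_%d.hisat2.txt", 1:2)), collapse = ";"),
            paste(file.path(s, sprintf("sample_%d.fc.summary", 1:2)), collapse = ";"),
            sep = "\t")
    }, character(1))), manifest_path)

  # Golden expectations, hand-computed from the defining formulas; the
  # transcript diversity of "bravo" is frozen from the independent
  # eigendecomposition of the centered 3 x 3 proportion matrix.
  golden <- data.frame(
    species_id = sp,
    AdjN50Contig = c(1, 0.5, 0),
    AdjN50Scaffold = c(1, 0.5, 0),
    UngapRate = c(1, 0.75, 0),
    UnimapRate = c(0.88, 0.68, 0.48),
    MapRate = c(0.95, 0.84, 0.70),
    MultiMapRate = c(0.93, 0.84, 0.78),
    TranscriptDiversity = c(1, 0.645751311064591, 0),
    QuantRate = c(0.78, 0.58, 0.38),
    QuantRateAbs = c(0.93, 0.76, 0.51),
    QuantRateAmb = c(0.87, 0.84, 0.89),
    MQI = c(0.92, 2.36 / 3, 1.96 / 3),
    QQI = c(0.86, 2.18 / 3, 1.78 / 3),
    stringsAsFactors = FALSE
  )
  golden$index <- rowMeans(golden[REFQUAL_INDICATORS])
  list(dir = dir, manifest_path = manifest_path, golden = golden)
}
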