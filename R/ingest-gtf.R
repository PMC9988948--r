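#' Profile a GTF gene annotation
#'
#' Tabulates gene counts per biotype and computes the annotation-structure
#' statistics used in the diversity and quantification diagnostics: number of
#' distinct genes, mean gene span, and the fractions of the genome covered by
#' merged gene spans (genic fraction) and merged exons (exonic fraction).
#'
#' Coordinates are treated as 1-based inclusive (span length = end - start + 1)
#' and interval merging ignores strand, per sequence. The biotype is read from
#' the `gene_biotype` attribute, falling back to `gene_type`; a gene with no
#' biotype attribute is counted under `"unannotated_biotype"`. When a gene's
#' lines disagree on biotype, the first-seen value wins and a warning is
#' emitted. Gene spans come from `gene` feature lines when present, otherwise
#' from the per-`gene_id` range over all feature lines — both encodings of the
#' same annotation yield the same profile.
#'
#' @param gtf Path to a GTF file (GFF2 attribute syntax).
#' @param genome_size Genome size in base pairs (denominator of the genomic
#'   fractions).
#' @param species_id Species label attached to the profile.
#' @return A `biotype_profile` record: list with `species_id`,
#'   `biotype_counts` (named integer vector), `n_genes`, `mean_gene_length`,
#'   `genic_fraction`, `exonic_fraction`.
#' @export
profile_gtf <- function(gtf, genome_size, species_id = NA_character_) {
  check_scalar_count(genome_size, "genome_size", positive = TRUE)
  if (!file.exists(gtf)) io_error(sprintf("GTF not found: %s", gtf))
  gr <- tryCatch(rtracklayer::import(gtf, format = "gtf"),
                 error = function(e) parse_error(sprintf("malformed GTF %s: %s",
                                                         gtf, conditionMessage(e))))
  mc <- S4Vectors::mcols(gr)
  if (!"gene_id" %in% names(mc)) {
    parse_error(sprintf("GTF %s carries no gene_id attribute", gtf))
  }
  gene_id <- as.character(mc$gene_id)
  if (all(is.na(gene_id))) parse_error(sprintf("GTF %s: all gene_id missing", gtf))
  feature <- as.character(mc$type)

  biotype <- rep(NA_character_, length(gr))
  for (attr in c("gene_biotype", "gene_type")) {
    if (attr %in% names(mc)) {
      take <- is.na(biotype) & !is.na(mc[[attr]])
      biotype[take] <- as.character(mc[[attr]][take])
    }
  }

  # Per-gene biotype, first-seen wins; warn on conflicts.
  has_bt <- !is.na(biotype) & !is.na(gene_id)
  if (any(has_bt)) {
    conflicts <- tapply(biotype[has_bt], gene_id[has_bt],
                        function(b) length(unique(b)) > 1L)
    if (any(conflicts)) {
      warning(sprintf("GTF %s: conflicting biotypes for gene(s) %s; first-seen wins",
                      gtf, paste(names(conflicts)[conflicts], collapse = ", ")),
              call. = FALSE)
    }
  }
  gene_bt <- biotype[has_bt][!duplicated(gene_id[has_bt])]
  names(gene_bt) <- gene_id[has_bt][!duplicated(gene_id[has_bt])]

  # Gene spans: prefer explicit gene lines; otherwise derive from all lines.
  gene_rows <- which(!is.na(feature) & feature == "gene" & !is.na(gene_id))
  if (length(gene_rows)) {
    keep <- gene_rows[!duplicated(gene_id[gene_rows])]
    spans <- gr[keep]
    names(spans) <- gene_id[keep]
  } else {
    ok <- !is.na(gene_id)
    spl <- S4Vectors::split(gr[ok], gene_id[ok])
    rng <- unlist(range(spl, ignore.strand = TRUE))
    spans <- rng[!duplicated(names(rng))]
  }
  ids <- names(spans)
  n_genes <- length(ids)
  if (n_genes == 0L) parse_error(sprintf("GTF %s contains no genes", gtf))

  bt_of <- gene_bt[ids]
  bt_of[is.na(bt_of)] <- "unannotated_biotype"
  biotype_counts <- table(bt_of)
  biotype_counts <- setNames(as.integer(biotype_counts), names(biotype_counts))
  biotype_counts <- biotype_counts[order(names(biotype_counts))]

  genic_bp <- sum(as.numeric(GenomicRanges::width(
    GenomicRanges::reduce(spans, ignore.strand = TRUE))))
  exon_rows <- which(!is.na(feature) & feature == "exon")
  exonic_bp <- if (length(exon_rows)) {
    sum(as.numeric(GenomicRanges::width(
      GenomicRanges::reduce(gr[exon_rows], ignore.strand = TRUE))))
  } else 0
  if (genic_bp > genome_size) {
    validation_error(sprintf("GTF %s: merged gene span (%.0f bp) exceeds genome_size",
                             gtf, genic_bp))
  }

  structure(list(
    species_id = species_id,
    biotype_counts = biotype_counts,
    n_genes = n_genes,
    mean_gene_length = mean(as.numeric(GenomicRanges::width(spans))),
    genic_fraction = genic_bp / genome_size,
    exonic_fraction = exonic_bp / genome_size
  ), class = "biotype_profile")
}
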