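# Shared builders for in-memory records and on-disk text fixtures.

ms <- function(total, unique, multi, unmapped, sample_id = "s1",
               species_id = "sp") {
  refqual:::new_mapping_summary(sample_id, species_id, total, unique, multi,
                                unmapped)
}

qs <- function(counts, sample_id = "s1", species_id = "sp") {
  refqual:::new_quant_summary(sample_id, species_id, counts)
}

bp <- function(species_id, counts, n_genes = sum(counts),
               mean_gene_length = 1000, genic_fraction = 0.1,
               exonic_fraction = 0.05) {
  structure(list(species_id = species_id, biotype_counts = counts,
                 n_genes = n_genes, mean_gene_length = mean_gene_length,
                 genic_fraction = genic_fraction,
                 exonic_fraction = exonic_fraction),
            class = "biotype_profile")
}

asm <- function(species_id, genome_size, contig_n50, scaffold_n50,
                spanned_gaps) {
  refqual:::new_assembly_stats(species_id, genome_size, contig_n50,
                               scaffold_n50, spanned_gaps)
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Random partitioned mapping counts: total split into unique/multi/unmapped.
random_partition <- function(total = 1000L) {
  cut1 <- sample.int(total + 1L, 1L) - 1L
  cut2 <- sample.int(total - cut1 + 1L, 1L) - 1L
  c(unique = cut1, multi = cut2, unmapped = total - cut1 - cut2)
}

# Write a toy GTF from a data.frame of gene features (chr, start, end,
# strand, gene_id, biotype) plus optional exon rows.
write_gtf_lines <- function(genes, exons = NULL, gene_lines = TRUE) {
  lines <- character(0)
  if (gene_lines) {
    lines <- sprintf('%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_biotype "%s";',
                     genes$chr, genes$start, genes$end, genes$strand,
                     genes$gene_id, genes$biotype)
  }
  if (!is.null(exons)) {
    lines <- c(lines, sprintf(
      '%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_biotype "%s"; transcript_id "%s.t1";',
      exons$chr, exons$start, exons$end, exons$strand, exons$gene_id,
      exons$biotype, exons$gene_id))
  }
  write_tmp(lines, ".gtf")
}

# Memoized 50-species synthetic cohort shared by the end-to-end tests.
.refqual_test_env <- new.env(parent = emptyenv())
acceptance_cohort <- function() {
  if (is.null(.refqual_test_env$cohort)) {
    dir <- file.path(tempdir(), "refqual_accept_cohort")
    sim <- simulate_cohort(n_species = 50, n_samples = 10, seed = 20260927,
                           out_dir = dir)
    fit <- refqual(sim$manifest_path)
    .refqual_test_env$cohort <- list(sim = sim, fit = fit)
  }
  .refqual_test_env$cohort
}
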