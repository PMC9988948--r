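#' Canonical Ensembl-style biotype vocabulary
#'
#' The 30 gene-biotype names the proportion matrix is initialized with.
#' Biotypes observed outside this vocabulary are kept verbatim, never
#' collapsed.
#'
#' @return Character vector of 30 biotype names.
#' @export
ensembl_biotypes <- function() {
  c("protein_coding", "lncRNA", "miRNA", "snRNA", "snoRNA", "scaRNA",
    "rRNA", "tRNA", "misc_RNA", "ribozyme", "sRNA", "scRNA", "vault_RNA",
    "Mt_rRNA", "Mt_tRNA", "processed_pseudogene", "unprocessed_pseudogene",
    "transcribed_processed_pseudogene", "transcribed_unprocessed_pseudogene",
    "translated_processed_pseudogene", "unitary_pseudogene", "pseudogene",
    "polymorphic_pseudogene", "rRNA_pseudogene", "IG_V_gene", "IG_C_gene",
    "TR_V_gene", "TR_C_gene", "TEC", "nonsense_mediated_decay")
}

# Dirichlet draw via normalized gammas.
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate a complete on-disk cohort
#'
#' Writes a full synthetic input set — manifest, per-species assembly
#' statistics, HISAT2-style paired-end alignment summaries, featureCounts-style
#' quantification summaries, and toy GTF annotations — governed by two latent
#' gradients on \[0, 1\]: a scalar quality `q` per species and an annotation
#' diversity `d` (defaulting to `q`, so one latent drives genome and
#' annotation quality together; pass a decoupled `latent_diversity` to break
#' the tie).
#'
#' The generative directions mirror what is observed on real cohorts:
#' spanned-gap counts fall and adjusted N50 rises with `q`; the
#' uniquely-mapped share of reads rises with `q`; the assigned share of
#' quantified reads rises with `q`; the no-feature failure share falls and
#' the ambiguity failure share rises with the annotation latent `d` (denser
#' genic annotation assigns more reads but creates more overlap ambiguity);
#' biotype richness and evenness rise with `d` via a Dirichlet concentration
#' gradient over the 30-biotype vocabulary.
#'
#' @param n_species Number of species.
#' @param n_samples Samples per species.
#' @param seed Integer seed fixing all randomness end-to-end; identical calls
#'   produce byte-identical file trees.
#' @param out_dir Directory to write the cohort into (created if needed).
#' @param genome_size_range Log-uniform range for genome sizes, base pairs.
#' @param latent_quality Optional numeric vector of `q_i` in \[0, 1\];
#'   default equally spaced 0..1.
#' @param latent_diversity Optional `d_i`; default equal to `q_i`.
#' @param total_units Read units per alignment summary.
#' @param quant_total Read units per quantification summary.
#' @param n_genes_range Range of gene counts per toy GTF.
#' @param concentration Dirichlet concentration of the mapping/quant
#'   compositional draws (higher = less sample noise).
#' @param biotype_vocab Biotype vocabulary for the toy GTFs.
#' @return List with `dir`, `manifest_path`, and `latents` (data.frame of
#'   species_id, q, d, genome_size, genic_fraction target).
#' @export
simulate_cohort <- function(n_species = 50L, n_samples = 10L, seed = 1L,
                            out_dir = tempfile("cohort"),
                            genome_size_range = c(5e7, 2e9),
                            latent_quality = NULL, latent_diversity = NULL,
                            total_units = 1e6, quant_total = 8e5,
                            n_genes_range = c(600L, 1200L),
                            concentration = 300,
                            biotype_vocab = ensembl_biotypes()) {
  check_scalar_count(n_species, "n_species", positive = TRUE)
  check_scalar_count(n_samples, "n_samples", positive = TRUE)
  if (!is.numeric(genome_size_range) || length(genome_size_range) != 2L ||
      genome_size_range[1] <= 0 || diff(genome_size_range) < 0 ||
      genome_size_range[2] > 2^31 - 2) {
    domain_error("genome_size_range must be increasing, positive, below 2^31")
  }
  q <- latent_quality %||% (if (n_species == 1L) 0.5 else
    seq(0, 1, length.out = n_species))
  d <- latent_diversity %||% q
  if (length(q) != n_species || length(d) != n_species ||
      any(q < 0 | q > 1) || any(d < 0 | d > 1)) {
    domain_error("latents must be length n_species, in [0, 1]")
  }
  if (length(biotype_vocab) < 2L) domain_error("biotype vocabulary too small")

  set.seed(as.integer(seed))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sp_ids <- sprintf("species_%02d", seq_len(n_species))

  # Biotype composition endpoints: a poorly annotated genome is almost all
  # protein_coding; a richly annotated one spreads over the vocabulary with a
  # geometric tail. A species' mean composition interpolates with d.
  tail_w <- 0.8^seq_len(length(biotype_vocab) - 1)
  base_rich <- c(60, 8 * tail_w) / sum(c(60, 8 * tail_w))
  base_poor <- c(0.97, 0.03 * tail_w / sum(tail_w))

  rows <- vector("list", n_species)
  latents <- data.frame(species_id = sp_ids, q = q, d = d,
                        genome_size = NA_real_, genic_fraction = NA_real_,
                        stringsAsFactors = FALSE)
  for (i in seq_len(n_species)) {
    sp <- sp_ids[i]
    sp_dir <- file.path(out_dir, sp)
    dir.create(sp_dir, showWarnings = FALSE)

    # --- assembly statistics ---
    G <- round(exp(runif(1, log(genome_size_range[1]), log(genome_size_range[2]))))
    contig_ratio <- exp(log(1e-4) + q[i] * (log(0.25) - log(1e-4)) + rnorm(1, 0, 0.3))
    contig_ratio <- min(contig_ratio, 0.9)
    scaffold_ratio <- min(contig_ratio * exp(runif(1, log(1.5), log(8))), 1)
    gaps <- rpois(1, exp(log(1.5e5) + q[i] * (log(30) - log(1.5e5))))
    asm_path <- file.path(sp_dir, "assembly.tsv")
    writeLines(c("genome_size\tcontig_n50\tscaffold_n50\tspanned_gaps",
                 sprintf("%d\t%d\t%d\t%d", G, max(1L, round(contig_ratio * G)),
                         max(1L, round(scaffold_ratio * G)), gaps)), asm_path)
    latents$genome_size[i] <- G

    # --- alignment summaries (HISAT2 paired dialect) ---
    unique_share <- 0.50 + 0.45 * q[i]
    rest <- 1 - unique_share
    map_paths <- character(n_samples)
    for (s in seq_len(n_samples)) {
      shares <- rdirichlet1(concentration *
                              c(unique_share, rest * 0.45, rest * 0.55))
      counts <- as.vector(rmultinom(1, total_units, shares))
      map_paths[s] <- file.path(sp_dir, sprintf("sample_%02d.hisat2.txt", s))
      write_hisat2_summary(map_paths[s], total = total_units,
                           unique = counts[1], multi = counts[2],
                           unmapped = counts[3])
    }

    # --- quantification summaries (featureCounts dialect) ---
    gf <- 0.05 + 0.70 * d[i]
    abs_share <- 0.05 + 0.35 * (1 - d[i])
    amb_share <- 0.03 + 0.22 * d[i]
    success_budget <- 1 - abs_share - amb_share - 0.02
    assigned_share <- success_budget * (0.70 + 0.30 * q[i])
    other_share <- 0.02 + success_budget - assigned_share
    quant_paths <- character(n_samples)
    for (s in seq_len(n_samples)) {
      shares <- rdirichlet1(concentration *
                              c(assigned_share, abs_share, amb_share, other_share))
      counts <- as.vector(rmultinom(1, quant_total, shares))
      unmapped_extra <- rbinom(1, quant_total, 0.08)
      quant_paths[s] <- file.path(sp_dir, sprintf("sample_%02d.fc.summary", s))
      writeLines(c(sprintf("Status\tsample_%02d.bam", s),
                   sprintf("Assigned\t%d", counts[1]),
                   sprintf("Unassigned_Unmapped\t%d", unmapped_extra),
                   sprintf("Unassigned_NoFeatures\t%d", counts[2]),
                   sprintf("Unassigned_Ambiguity\t%d", counts[3]),
                   sprintf("Unassigned_Secondary\t%d", counts[4])),
                 quant_paths[s])
    }

    # --- toy GTF ---
    n_genes <- sample(seq(n_genes_range[1], n_genes_range[2]), 1)
    mean_bt <- (1 - d[i]) * base_poor + d[i] * base_rich
    bt_p <- rdirichlet1(mean_bt * (20 + 180 * d[i]))
    bt_counts <- as.vector(rmultinom(1, n_genes, bt_p))
    gtf_path <- file.path(sp_dir, "annotation.gtf")
    write_toy_gtf(gtf_path, biotype_vocab, bt_counts, genome_size = G,
                  genic_fraction = gf)
    latents$genic_fraction[i] <- gf

    rel <- function(p) substring(p, nchar(out_dir) + 2L)
    rows[[i]] <- sprintf("%s\t%s\t%s\t%s\t%s\t%s", sp, sp,
                         rel(asm_path), rel(gtf_path),
                         paste(rel(map_paths), collapse = ";"),
                         paste(rel(quant_paths), collapse = ";"))
  }

  manifest_path <- file.path(out_dir, "manifest.tsv")
  writeLines(c(paste("species_id", "display_name", "assembly_stats", "gtf",
                     "mapping_summaries", "quant_summaries", sep = "\t"),
               unlist(rows)), manifest_path)
  list(dir = out_dir, manifest_path = manifest_path, latents = latents)
}

write_hisat2_summary <- function(path, total, unique, multi, unmapped) {
  pct <- function(x) sprintf("%.2f", 100 * x / total)
  overall <- sprintf("%.2f", 100 * (total - unmapped) / total)
  writeLines(c(
    sprintf("%d reads; of these:", total),
    sprintf("  %d (100.00%%) were paired; of these:", total),
    sprintf("    %d (%s%%) aligned concordantly 0 times", unmapped, pct(unmapped)),
    sprintf("    %d (%s%%) aligned concordantly exactly 1 time", unique, pct(unique)),
    sprintf("    %d (%s%%) aligned concordantly >1 times", multi, pct(multi)),
    sprintf("%s%% overall alignment rate", overall)
  ), path)
}

# Genes laid out sequentially over chromosomes so the merged span hits the
# requested genic fraction; each gene gets one transcript with 1-3 exons.
write_toy_gtf <- function(path, vocab, counts, genome_size, genic_fraction) {
  n_genes <- sum(counts)
  biotypes <- rep(vocab[seq_along(counts)], counts)
  if (n_genes == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  biotypes <- sample(biotypes)  # shuffle so biotype doesn't track position
  n_chr <- max(1L, ceiling(genome_size / 2e8))
  chr_len <- floor(genome_size / n_chr)
  genes_per_chr <- ceiling(n_genes / n_chr)
  lines <- character(0)
  gi <- 0L
  for (ch in seq_len(n_chr)) {
    n_here <- min(genes_per_chr, n_genes - gi)
    if (n_here <= 0L) break
    span_total <- genic_fraction * chr_len
    gap <- max(1, floor((chr_len - span_total) / (n_here + 1)))
    mean_len <- max(200, floor(span_total / n_here))
    pos <- 1
    for (k in seq_len(n_here)) {
      gi <- gi + 1L
      len <- max(200, round(mean_len * exp(rnorm(1, 0, 0.25))))
      start <- pos + gap
      end <- min(start + len - 1, chr_len)
      if (start >= end) { start <- pos + 1; end <- start + 199 }
      gid <- sprintf("g%05d", gi)
      strand <- if (gi %% 2 == 0) "+" else "-"
      attr_g <- sprintf('gene_id "%s"; gene_biotype "%s";', gid, biotypes[gi])
      lines <- c(lines, sprintf("chr%d\trefqual\tgene\t%d\t%d\t.\t%s\t.\t%s",
                                ch, start, end, strand, attr_g))
      n_ex <- sample(1:3, 1)
      bounds <- sort(unique(round(seq(start, end, length.out = 2 * n_ex))))
      for (e in seq_len(n_ex)) {
        es <- bounds[2 * e - 1]
        ee <- if (2 * e <= length(bounds)) bounds[2 * e] else end
        lines <- c(lines, sprintf(
          "chr%d\trefqual\texon\t%d\t%d\t.\t%s\t.\t%s transcript_id \"%s.t1\";",
          ch, es, ee, strand, attr_g, gid))
      }
      pos <- end
    }
  }
  writeLines(lines, path)
  invisible(path)
}
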