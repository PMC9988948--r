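#' Parse an alignment summary report
#'
#' Extracts per-sample read-unit counts — total, uniquely mapped, multi-mapped
#' and unmapped — from an aligner's textual summary. Two dialects are
#' supported:
#'
#' * `"hisat2"`: the paired-end summary text printed by HISAT2/Bowtie2-style
#'   aligners (`N reads; of these:` followed by `aligned concordantly
#'   0 / exactly 1 / >1 times` lines, or the single-end `aligned 0 / exactly
#'   1 / >1 times` variant). The read unit is the unit the aligner reports
#'   (pairs for paired-end input).
#' * `"samtools_stats"`: `SN` key:value lines from `samtools stats`. This
#'   dialect reports mapped/unmapped totals only; unique and multi-mapped
#'   counts are recorded as `NA` (never inferred), so only the overall
#'   mapping rate is available for such samples.
#'
#' Counts from the hisat2 dialect must satisfy the partition
#' `unique + multi + unmapped == total`; a violation is a validation error
#' reporting the residual. A truncated or unrecognized file is a parse error,
#' never silent zeros.
#'
#' @param path Path to the summary text file.
#' @param sample_id Sample label attached to the record; defaults to the file
#'   name without extension.
#' @param species_id Species label attached to the record.
#' @param dialect `"auto"` (default, sniff from content), `"hisat2"`, or
#'   `"samtools_stats"`.
#' @return A `mapping_summary` record: list with `sample_id`, `species_id`,
#'   `total_units`, `unique_units`, `multi_units`, `unmapped_units`, `unit`
#'   (`"pair"` or `"read"`), `dialect`.
#' @export
parse_alignment_summary <- function(path, sample_id = NULL,
                                    species_id = NA_character_,
                                    dialect = c("auto", "hisat2", "samtools_stats")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) io_error(sprintf("alignment summary not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  if (dialect == "auto") {
    dialect <- if (any(grepl("reads; of these:", lines))) "hisat2"
      else if (any(grepl("^SN\t", lines))) "samtools_stats"
      else parse_error(sprintf(
        "unrecognized alignment summary dialect in %s; supported: hisat2, samtools_stats",
        path))
  }
  if (dialect == "hisat2") parse_hisat2_summary(lines, path, sample_id, species_id)
  else parse_samtools_stats(lines, path, sample_id, species_id)
}

new_mapping_summary <- function(sample_id, species_id, total_units, unique_units,
                                multi_units, unmapped_units, unit = "read",
                                dialect = NA_character_) {
  check_scalar_count(total_units, "total_units", positive = TRUE)
  for (nm in c("unique_units", "multi_units", "unmapped_units")) {
    v <- get(nm)
    if (!is.na(v)) check_scalar_count(v, nm)
  }
  if (!is.na(unique_units) && !is.na(multi_units) && !is.na(unmapped_units)) {
    residual <- total_units - (unique_units + multi_units + unmapped_units)
    if (residual != 0) {
      validation_error(sprintf(
        "mapping counts do not partition total (residual %d for sample %s)",
        as.integer(residual), sample_id))
    }
  }
  structure(list(sample_id = sample_id, species_id = species_id,
                 total_units = as.numeric(total_units),
                 unique_units = as.numeric(unique_units),
                 multi_units = as.numeric(multi_units),
                 unmapped_units = as.numeric(unmapped_units),
                 unit = unit, dialect = dialect),
            class = "mapping_summary")
}

first_count <- function(lines, pattern, path) {
  hit <- grep(pattern, lines, value = TRUE)
  if (length(hit) == 0L) {
    parse_error(sprintf("truncated or unsupported alignment summary %s: no line matching '%s'",
                        path, pattern))
  }
  as.numeric(sub("^\\s*(\\d+).*$", "\\1", hit[[1]]))
}

parse_hisat2_summary <- function(lines, path, sample_id, species_id) {
  total <- first_count(lines, "^\\s*\\d+ reads; of these:", path)
  paired <- any(grepl("were paired; of these:", lines))
  prefix <- if (paired) "aligned concordantly " else "aligned "
  unmapped <- first_count(lines, paste0("^\\s*\\d+ \\([0-9.]+%\\) ", prefix, "0 times"), path)
  unique <- first_count(lines, paste0("^\\s*\\d+ \\([0-9.]+%\\) ", prefix, "exactly 1 time"), path)
  multi <- first_count(lines, paste0("^\\s*\\d+ \\([0-9.]+%\\) ", prefix, ">1 times"), path)
  new_mapping_summary(sample_id, species_id, total, unique, multi, unmapped,
                      unit = if (paired) "pair" else "read", dialect = "hisat2")
}

parse_samtools_stats <- function(lines, path, sample_id, species_id) {
  sn <- lines[grepl("^SN\t", lines)]
  if (length(sn) == 0L) parse_error(sprintf("no SN lines in %s", path))
  get_sn <- function(key) {
    hit <- sn[startsWith(sn, paste0("SN\t", key, ":"))]
    if (length(hit) == 0L) {
      parse_error(sprintf("truncated samtools-stats summary %s: no '%s'", path, key))
    }
    as.numeric(strsplit(hit[[1]], "\t", fixed = TRUE)[[1]][3])
  }
  total <- get_sn("raw total sequences")
  unmapped <- get_sn("reads unmapped")
  new_mapping_summary(sample_id, species_id, total,
                      unique_units = NA_real_, multi_units = NA_real_,
                      unmapped_units = unmapped,
                      unit = "read", dialect = "samtools_stats")
}
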