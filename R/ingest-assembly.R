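#' Parse per-species assembly statistics
#'
#' Reads genome size, contig/scaffold N50 and the spanned-gap count for one
#' species. Two dialects are supported: a flat TSV with header columns
#' `genome_size`, `contig_n50`, `scaffold_n50`, `spanned_gaps` (the canonical
#' dialect; an optional `species_id` column selects the row in multi-row
#' tables), and an ENA-style XML document carrying TAG/VALUE attribute pairs
#' (`total-length`, `contig-n50`, `scaffold-n50`, `spanned-gaps`).
#'
#' All units are base pairs (counts for gaps). A value of `NA` for any
#' required field marks the species assembly-stats-missing rather than
#' defaulting to zero.
#'
#' @param path Path to the statistics file.
#' @param species_id Species label attached to the record (and used to select
#'   a row in multi-row TSV tables carrying a `species_id` column).
#' @param dialect `"tsv"`, `"xml"`, or `"auto"` (sniff from content).
#' @return An `assembly_stats` record (named list) with fields `species_id`,
#'   `genome_size`, `contig_n50`, `scaffold_n50`, `spanned_gaps`; or `NULL`
#'   with a warning when a required field is declared `NA` in the source.
#' @export
parse_assembly_stats <- function(path, species_id = NA_character_,
                                 dialect = c("auto", "tsv", "xml")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) io_error(sprintf("assembly stats not found: %s", path))
  if (dialect == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    dialect <- if (length(first) && grepl("^\\s*<", first)) "xml" else "tsv"
  }
  vals <- if (dialect == "tsv") {
    read_assembly_tsv(path, species_id)
  } else {
    read_assembly_xml(path)
  }
  required <- c("genome_size", "contig_n50", "scaffold_n50", "spanned_gaps")
  missing_fields <- setdiff(required, names(vals))
  if (length(missing_fields)) {
    parse_error(sprintf("assembly stats %s: missing field(s) %s", path,
                        paste(missing_fields, collapse = ", ")))
  }
  if (anyNA(vals[required])) {
    warning(sprintf("assembly stats %s: NA in %s; species marked assembly-stats-missing",
                    path, paste(required[is.na(vals[required])], collapse = ", ")),
            call. = FALSE)
    return(NULL)
  }
  new_assembly_stats(species_id,
                     genome_size = vals[["genome_size"]],
                     contig_n50 = vals[["contig_n50"]],
                     scaffold_n50 = vals[["scaffold_n50"]],
                     spanned_gaps = vals[["spanned_gaps"]])
}

# Constructor enforcing the record's invariants.
new_assembly_stats <- function(species_id, genome_size, contig_n50,
                               scaffold_n50, spanned_gaps) {
  check_scalar_count(genome_size, "genome_size", positive = TRUE)
  check_scalar_count(contig_n50, "contig_n50", positive = TRUE)
  check_scalar_count(scaffold_n50, "scaffold_n50", positive = TRUE)
  check_scalar_count(spanned_gaps, "spanned_gaps")
  if (contig_n50 > genome_size) {
    validation_error("contig_n50 exceeds genome_size")
  }
  if (scaffold_n50 > genome_size) {
    validation_error("scaffold_n50 exceeds genome_size")
  }
  structure(list(species_id = species_id,
                 genome_size = as.numeric(genome_size),
                 contig_n50 = as.numeric(contig_n50),
                 scaffold_n50 = as.numeric(scaffold_n50),
                 spanned_gaps = as.numeric(spanned_gaps)),
            class = "assembly_stats")
}

read_assembly_tsv <- function(path, species_id) {
  df <- tryCatch(
    read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) parse_error(sprintf("malformed assembly TSV %s: %s",
                                            path, conditionMessage(e)))
  )
  if (nrow(df) == 0L) parse_error(sprintf("assembly TSV %s has no data rows", path))
  if (nrow(df) > 1L) {
    if (!"species_id" %in% names(df) || is.na(species_id)) {
      parse_error(sprintf("assembly TSV %s has multiple rows; species_id column required", path))
    }
    df <- df[df$species_id == species_id, , drop = FALSE]
    if (nrow(df) != 1L) {
      parse_error(sprintf("assembly TSV %s: species '%s' not found", path, species_id))
    }
  }
  numify <- function(x) {
    if (length(x) != 1L || is.na(x)) return(NA_real_)
    if (is.numeric(x)) return(as.numeric(x))
    x <- gsub(",", "", trimws(as.character(x)), fixed = TRUE)
    if (toupper(x) %in% c("NA", "")) return(NA_real_)
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) parse_error(sprintf("assembly TSV %s: non-numeric value '%s'", path, x))
    v
  }
  fields <- intersect(c("genome_size", "contig_n50", "scaffold_n50", "spanned_gaps"),
                      names(df))
  setNames(vapply(fields, function(f) numify(df[[f]][1]), numeric(1)), fields)
}

# Minimal ENA-dialect reader: <ASSEMBLY_ATTRIBUTE><TAG>..</TAG><VALUE>..</VALUE>
read_assembly_xml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) parse_error(sprintf("malformed XML %s: %s",
                                                          path, conditionMessage(e))))
  tags <- xml2::xml_text(xml2::xml_find_all(doc, ".//ASSEMBLY_ATTRIBUTE/TAG"))
  values <- xml2::xml_text(xml2::xml_find_all(doc, ".//ASSEMBLY_ATTRIBUTE/VALUE"))
  if (length(tags) == 0L || length(tags) != length(values)) {
    parse_error(sprintf("XML %s: no TAG/VALUE assembly attributes", path))
  }
  lookup <- c("total-length" = "genome_size", "contig-n50" = "contig_n50",
              "scaffold-n50" = "scaffold_n50", "spanned-gaps" = "spanned_gaps")
  keep <- tolower(tags) %in% names(lookup)
  out <- suppressWarnings(as.numeric(gsub(",", "", values[keep])))
  names(out) <- lookup[tolower(tags)[keep]]
  out[!duplicated(names(out))]
}
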