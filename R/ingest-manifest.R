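#' Read a cohort manifest
#'
#' The manifest is a TSV with one row per species and columns `species_id`,
#' `display_name`, `assembly_stats`, `gtf`, `mapping_summaries`
#' (semicolon-separated paths), `quant_summaries` (semicolon-separated paths),
#' plus any number of optional numeric columns (e.g. `busco_completeness`,
#' `repeat_fraction`) carried through as diagnostics. Relative paths are
#' resolved against the manifest's directory. Empty cells denote absent
#' artifacts and are recorded as missing, never as zeros.
#'
#' @param path Path to the manifest TSV.
#' @return A `refqual_manifest` object: a list with `species` (a list of
#'   per-species records with resolved paths and a `missing` character vector
#'   naming absent artifact classes) and `optional_columns` (a data.frame of
#'   the extra numeric columns, if any).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) io_error(sprintf("manifest not found: %s", path))
  df <- tryCatch(
    read.delim(path, sep = "\t", stringsAsFactors = FALSE,
               check.names = FALSE, colClasses = "character"),
    error = function(e) parse_error(sprintf("malformed manifest %s: %s", path,
                                            conditionMessage(e)))
  )
  required <- c("species_id", "display_name", "assembly_stats", "gtf",
                "mapping_summaries", "quant_summaries")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    parse_error(sprintf("manifest header (line 1) lacks column(s): %s",
                        paste(missing_cols, collapse = ", ")))
  }
  if (nrow(df) == 0L) validation_error("manifest has no species rows")
  if (anyDuplicated(df$species_id)) {
    dup <- unique(df$species_id[duplicated(df$species_id)])
    validation_error(sprintf("duplicate species_id in manifest: %s",
                             paste(dup, collapse = ", ")))
  }

  base_dir <- dirname(normalizePath(path))
  extra_cols <- setdiff(names(df), required)
  optional <- NULL
  if (length(extra_cols)) {
    optional <- data.frame(species_id = df$species_id, stringsAsFactors = FALSE)
    for (col in extra_cols) {
      vals <- suppressWarnings(as.numeric(df[[col]]))
      bad <- !is.na(df[[col]]) & nzchar(df[[col]]) & !is.finite(vals)
      if (any(bad)) {
        validation_error(sprintf(
          "optional manifest column '%s' has non-numeric value(s): %s",
          col, paste(unique(df[[col]][bad]), collapse = ", ")))
      }
      vals[!nzchar(trimws(ifelse(is.na(df[[col]]), "", df[[col]])))] <- NA_real_
      optional[[col]] <- vals
    }
  }

  split_paths <- function(cell) {
    if (is.na(cell) || !nzchar(trimws(cell))) return(character(0))
    vapply(strsplit(trimws(cell), ";", fixed = TRUE)[[1]], resolve_path,
           character(1), base_dir = base_dir, USE.NAMES = FALSE)
  }

  species <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, , drop = FALSE]
    asm <- resolve_path(trimws(row$assembly_stats %||% ""), base_dir)
    gtf <- resolve_path(trimws(row$gtf %||% ""), base_dir)
    maps <- split_paths(row$mapping_summaries)
    quants <- split_paths(row$quant_summaries)
    missing <- character(0)
    if (is.na(asm) || !file.exists(asm)) missing <- c(missing, "assembly_stats")
    if (is.na(gtf) || !file.exists(gtf)) missing <- c(missing, "annotation")
    if (length(maps) == 0L || !all(file.exists(maps))) missing <- c(missing, "mapping")
    if (length(quants) == 0L || !all(file.exists(quants))) missing <- c(missing, "quantification")
    list(
      species_id = row$species_id,
      display_name = row$display_name,
      assembly_stats_path = if (is.na(asm) || !file.exists(asm)) NA_character_ else asm,
      gtf_path = if (is.na(gtf) || !file.exists(gtf)) NA_character_ else gtf,
      mapping_summary_paths = maps[file.exists(maps)],
      quant_summary_paths = quants[file.exists(quants)],
      missing = missing
    )
  })
  names(species) <- df$species_id
  structure(list(species = species, optional_columns = optional,
                 path = normalizePath(path)),
            class = "refqual_manifest")
}

#' @export
print.refqual_manifest <- function(x, ...) {
  n <- length(x$species)
  n_complete <- sum(vapply(x$species, function(s) length(s$missing) == 0L, logical(1)))
  cat(sprintf("refqual manifest: %d species (%d with all artifacts present)\n",
              n, n_complete))
  for (s in x$species) {
    flag <- if (length(s$missing)) paste0("  [missing: ",
                                          paste(s$missing, collapse = ", "), "]") else ""
    cat(sprintf("  %-20s %d mapping, %d quant summaries%s\n", s$species_id,
                length(s$mapping_summary_paths), length(s$quant_summary_paths), flag))
  }
  invisible(x)
}
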