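#' Parse a read-quantification status summary
#'
#' Reads a featureCounts-style `.summary` table: first column status-category
#' names, subsequent column(s) counts. Category names are normalized to
#' canonical lower-case keys (`Assigned` -> `assigned`,
#' `Unassigned_Ambiguity` -> `unassigned_ambiguity`,
#' `Unassigned_NoFeatures` -> `unassigned_no_features`,
#' `Unassigned_Unmapped` -> `unassigned_unmapped`); unknown categories are
#' preserved under their normalized names and contribute to the mapped-read
#' denominator (only `unassigned_unmapped` is excluded from it, being a
#' mapping rather than a quantification failure).
#'
#' @param path Path to the summary table.
#' @param sample_id Sample label; defaults to the count column header, falling
#'   back to the file name.
#' @param species_id Species label attached to the record.
#' @return A `quant_summary` record: list with `sample_id`, `species_id`,
#'   `category_counts` (named numeric vector over canonical keys).
#' @export
parse_quant_summary <- function(path, sample_id = NULL, species_id = NA_character_) {
  if (!file.exists(path)) io_error(sprintf("quant summary not found: %s", path))
  df <- tryCatch(
    read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) parse_error(sprintf("malformed quant summary %s: %s",
                                            path, conditionMessage(e)))
  )
  if (nrow(df) == 0L || ncol(df) < 2L) {
    parse_error(sprintf("empty or single-column quant summary: %s", path))
  }
  counts <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(counts)) {
    parse_error(sprintf("non-numeric count in quant summary %s", path))
  }
  keys <- normalize_quant_category(df[[1]])
  if (anyDuplicated(keys)) {
    validation_error(sprintf("duplicate status category in %s", path))
  }
  counts <- setNames(counts, keys)
  sample_id <- sample_id %||% {
    hdr <- names(df)[2]
    if (nzchar(hdr) && tolower(hdr) != "count") sub("\\.bam$", "", basename(hdr))
    else sub("\\.[^.]*$", "", basename(path))
  }
  new_quant_summary(sample_id, species_id, counts)
}

new_quant_summary <- function(sample_id, species_id, category_counts) {
  if (!is.numeric(category_counts) || is.null(names(category_counts)) ||
      any(!nzchar(names(category_counts)))) {
    domain_error("category_counts must be a named numeric vector")
  }
  if (anyNA(category_counts) || any(category_counts < 0)) {
    validation_error("negative or missing status-category count")
  }
  if (sum(category_counts) <= 0) {
    validation_error("quant summary has zero total count")
  }
  required <- c("assigned", "unassigned_ambiguity", "unassigned_no_features")
  absent <- setdiff(required, names(category_counts))
  if (length(absent)) {
    validation_error(sprintf("quant summary lacks required categories: %s",
                             paste(absent, collapse = ", ")))
  }
  structure(list(sample_id = sample_id, species_id = species_id,
                 category_counts = category_counts),
            class = "quant_summary")
}

# "Unassigned_NoFeatures" -> "unassigned_no_features"; camel humps to snake.
normalize_quant_category <- function(x) {
  x <- gsub("([a-z0-9])([A-Z])", "\\1_\\2", trimws(x))
  tolower(x)
}
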