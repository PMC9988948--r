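#' Write / read the indicator table
#'
#' Serializes a ranked indicator report (or raw indicator matrix) to TSV with
#' a deterministic column order: `species_id`, the ten indicators in
#' canonical order, `MQI`, `QQI`, `index`, `rank`, then any passthrough
#' columns. Missing values are written as empty cells (never zeros) and
#' numeric values round-trip losslessly well below 1e-6.
#'
#' @param matrix data.frame from [rank_report()] or
#'   [assemble_indicator_matrix()].
#' @param path Output TSV path.
#' @return Invisibly, the normalized path written.
#' @export
write_indicator_table <- function(matrix, path) {
  df <- as.data.frame(matrix)
  lead <- c("species_id", REFQUAL_INDICATORS,
            intersect(c("MQI", "QQI", "index", "rank"), names(df)))
  df <- df[c(lead, setdiff(names(df), lead))]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), "", sprintf("%.10g", x))
  })
  ok <- tryCatch({
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) io_error(sprintf("cannot write indicator table to %s", path))
  invisible(path)
}

#' @rdname write_indicator_table
#' @export
read_indicator_table <- function(path) {
  if (!file.exists(path)) io_error(sprintf("indicator table not found: %s", path))
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
  for (col in setdiff(names(df), c("species_id", "build"))) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df
}
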