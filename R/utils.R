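# Internal helpers: classed error conditions and argument checks.

refqual_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "refqual_error", "error", "condition")))
}

parse_error <- function(msg) refqual_error(msg, "refqual_parse_error")
validation_error <- function(msg) refqual_error(msg, "refqual_validation_error")
domain_error <- function(msg) refqual_error(msg, "refqual_domain_error")
io_error <- function(msg) refqual_error(msg, "refqual_io_error")

check_scalar_count <- function(x, name, positive = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x < 0 ||
      x != round(x)) {
    domain_error(sprintf("'%s' must be a single non-negative integer", name))
  }
  if (positive && x <= 0) {
    domain_error(sprintf("'%s' must be positive", name))
  }
  invisible(as.numeric(x))
}

check_rates01 <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    domain_error(sprintf("'%s' must be rates in [0, 1]", name))
  }
  invisible(x)
}

# Resolve a possibly relative path against the directory of a manifest file.
resolve_path <- function(path, base_dir) {
  if (is.na(path) || !nzchar(path)) return(NA_character_)
  if (grepl("^(/|[A-Za-z]:)", path)) return(path)
  file.path(base_dir, path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
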