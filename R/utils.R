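# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Stop with a consistent schema-error class
#' @noRd
schema_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("heteroseq_schema_error", "error")))
}

#' Stop with a consistent configuration-error class
#' @noRd
config_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("heteroseq_config_error", "error")))
}

#' Write a data.frame as TSV with stable column order and no quoting
#' @noRd
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by write_tsv
#' @noRd
read_tsv <- function(path, ...) {
  if (!file.exists(path)) schema_error("file not found: ", path)
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

#' Format a number for deterministic text output (no scientific notation)
#' @noRd
fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), ".", format(round(x, digits), scientific = FALSE,
                               trim = TRUE, nsmall = 0))
}

#' Benjamini-Hochberg adjustment that tolerates NAs
#' @noRd
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}
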