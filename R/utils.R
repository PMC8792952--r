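#' @import data.table
#' @importFrom stats lm coef anova pnorm pt rbinom rpois runif rnorm var sd cor
#'   complete.cases setNames aggregate dnorm qt
#' @importFrom utils write.table read.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a data.frame as a TSV file with stable ordering
#'
#' Deterministic writer used by all command-line outputs: rows are emitted in
#' the order given (callers sort by stable keys first), numbers are not
#' rounded, and quoting is disabled so files are byte-reproducible.
#'
#' @param x data.frame or data.table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

hd_log <- function(..., verbose = getOption("herddiv.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[herddiv] ", ...)
  invisible(NULL)
}

stop_hd <- function(...) stop(..., call. = FALSE)
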