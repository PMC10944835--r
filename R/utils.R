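# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

# deterministic child seeds below 2^31, derived from a user seed
child_seed <- function(seed, k) {
  (as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647 + 1
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, guarded against cancellation
logdiffexp <- function(a, b) {
  d <- 1 - exp(b - a)
  if (d <= 0) return(-Inf)
  a + log(d)
}

#' Write a data frame as tab-separated text
#'
#' Plain TSV dialect used throughout the package: one header line, no
#' quoting, missing values written as "NA".
#'
#' @param x data frame.
#' @param path output file path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a tab-separated table written by [write_tsv()]
#'
#' Columns are matched by name downstream, so column order is free.
#'
#' @param path file path.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    na.strings = "NA", check.names = FALSE)
}
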