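`%||%` <- function(a, b) if (is.null(a)) b else a

#' Format a count with its percentage
#'
#' Renders `n (pct)` the way clinical characteristic tables print categorical
#' rows, e.g. `format_count_pct(10, 52)` gives `"10 (19.2)"`.
#'
#' @param n Count of positive findings.
#' @param total Number of subjects in the group.
#' @return Character scalar `"n (pct)"` with the percentage to one decimal.
#' @export
format_count_pct <- function(n, total) {
  stopifnot(is.numeric(n), is.numeric(total), total > 0, n >= 0, n <= total)
  sprintf("%d (%.1f)", as.integer(n), 100 * n / total)
}

#' Format a continuous summary as median with interquartile range
#'
#' @param x Numeric vector (missing values dropped).
#' @param digits Decimal places (default 2, as in clinical tables).
#' @return Character scalar `"median [Q1, Q3]"`.
#' @export
format_median_iqr <- function(x, digits = 2) {
  x <- x[!is.na(x)]
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  fmt <- paste0("%.", digits, "f")
  sprintf(paste0(fmt, " [", fmt, ", ", fmt, "]"), q[2], q[1], q[3])
}

# derive a stage seed from the pipeline seed; keeps values in 32-bit range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% .Machine$integer.max)
}
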