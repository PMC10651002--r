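#' Round half away from zero
#'
#' Report tables round percentages with halves away from zero (so 26.85
#' prints as 26.9), unlike [base::round()]'s round-half-even. Internal
#' values are never rounded; this is a formatting-stage helper.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# days-per-week and month-length constants used throughout; GA is kept in
# integer days internally so week-boundary comparisons are exact
DAYS_PER_WEEK <- 7L
DAYS_PER_MONTH <- 365.25 / 12

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_anccov <- function(msg, class) {
  rlang::abort(msg, class = c(class, "anccov_error"))
}
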