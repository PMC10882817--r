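# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Half-up rounding
#'
#' Rounds to the nearest value at the requested number of decimal digits,
#' resolving ties away from zero for positive input (0.5 -> 1). Used for all
#' printed percentages so that reported values match conventional manuscript
#' rounding rather than IEEE round-half-even.
#'
#' @param x numeric vector.
#' @param digits integer, number of decimal digits to keep.
#' @return numeric vector rounded half-up.
#' @export
halfUp <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Express a fraction as a percentage with half-up rounding
#'
#' @param fraction numeric fraction(s) in `[0, 1]`.
#' @param digits decimal digits of the percentage (0 gives integer percent).
#' @return numeric percentage(s).
#' @export
percentHalfUp <- function(fraction, digits = 0) {
  halfUp(100 * fraction, digits)
}

# Evaluate `code` under a fixed RNG seed, restoring global RNG state after.
withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Whole-number check tolerant of numeric storage.
isWholeNumber <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}

# Stop with a consistent message prefix.
failWith <- function(...) stop(..., call. = FALSE)
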