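# Small exact-arithmetic helpers. Primary scores are ratios of small
# integers (ones-count / dimension cardinality), so every index value is
# kept as an integer numerator over an integer denominator and converted
# to decimal only at display time.

gcd2 <- function(a, b) {
  while (b != 0) {
    r <- a %% b
    a <- b
    b <- r
  }
  a
}

lcm2 <- function(a, b) (a %/% gcd2(a, b)) * b

lcm_all <- function(x) Reduce(lcm2, x, accumulate = FALSE)

#' Round half away from zero
#'
#' Decimal rounding with exact ties going up (`0.005 -> 0.01`), the
#' convention used throughout for displayed index values. Base R's
#' `round()` rounds ties to even, which disagrees on exact half cases.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(c(0.005, 0.665, 7.665), 2)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Exact half-up rounding of num/den to 2 decimals using integer division
# only; num, den integer vectors (den > 0).
rat_display2 <- function(num, den) {
  ((200 * num + den) %/% (2 * den)) / 100
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_pmc <- function(msg, class) {
  stop(structure(
    class = c(class, "pmc_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
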