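#' Largest-remainder integer allocation
#'
#' Splits `n` into integer counts proportional to `p` (which must sum to 1)
#' so that the counts sum exactly to `n`. Floors each share, then hands the
#' remaining units to the largest fractional remainders (ties broken by
#' position, so the allocation is deterministic).
#'
#' @param n Non-negative integer total.
#' @param p Numeric vector of proportions summing to 1 (within 1e-9).
#' @return Integer vector of length `length(p)` summing to `n`.
#' @export
largest_remainder <- function(n, p) {
  stopifnot(n >= 0, all(p >= 0))
  if (abs(sum(p) - 1) > 1e-9) {
    stop("proportions must sum to 1 (got ", format(sum(p), digits = 12), ")")
  }
  shares <- n * p
  base <- floor(shares)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- shares - base
    give <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[give] <- base[give] + 1
  }
  as.integer(base)
}

#' Round half-up to a fixed number of decimals
#'
#' Base R `round()` rounds half to even; report tables use the commercial
#' half-up convention (14.07 -> 14.1).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Format a count with its percentage, "n (pct)" style
#'
#' @param n Count (numerator).
#' @param total Denominator.
#' @param digits Decimal places for the percentage (half-up).
#' @return Character vector like `"606 (14.1)"`.
#' @export
format_n_pct <- function(n, total, digits = 1) {
  pct <- round_half_up(100 * n / total, digits)
  sprintf("%d (%s)", as.integer(n), formatC(pct, format = "f", digits = digits))
}

# clamp to the 0-10 numeric rating scale
clamp_nrs <- function(x, lo = 0, hi = 10) pmin(pmax(x, lo), hi)

# path to a file shipped under inst/extdata
pkg_extdata <- function(...) {
  system.file("extdata", ..., package = "painpheno", mustWork = TRUE)
}

# derive a reproducible child seed (kept below 2^31) from a base seed
child_seed <- function(seed, k) {
  ((as.integer(seed) %% 1000003L) * 2011L + as.integer(k) * 7919L) %% 2147483629L
}
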