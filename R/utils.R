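# Calendar convention used throughout: one month = 30.4375 days (the mean
# Gregorian month), so a 3-month horizon cuts at 91.3125 days after the index
# prescription. Outcome windows are half-open, (index, index + t months], with
# an event on the boundary day counted inside the window.
MONTH_DAYS <- 30.4375

#' Convert follow-up horizons in months to days
#'
#' @param months numeric vector of horizons in months.
#' @return numeric vector of day cutoffs (fractional; a month is 30.4375 days).
#' @export
#' @examples
#' months_to_days(c(3, 6, 24))
months_to_days <- function(months) {
  stopifnot(is.numeric(months), all(months > 0))
  months * MONTH_DAYS
}

#' Round half away from zero
#'
#' Base `round()` rounds half to even; published tables round half up. Used
#' for all percentages the package prints.
#'
#' @param x numeric vector.
#' @param digits decimal places to keep.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Deterministic substream seeds: each module/replicate derives its own seed
# from the scenario seed so stages can be rerun independently. Kept strictly
# below 2^31 - 1.
derive_seed <- function(seed, offset) {
  s <- (as.double(seed) %% 1e6) * 2039 + 1009 * as.double(offset)
  as.integer(s %% (.Machine$integer.max - 1L)) + 1L
}

# stop() with a consistent call-free style
abort_prefiv <- function(...) stop(..., call. = FALSE)

# Integer uniform draw on [lo, hi] elementwise (vectorised, lo <= hi).
runif_int <- function(n, lo, hi) {
  lo + floor(runif(n) * (hi - lo + 1))
}
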