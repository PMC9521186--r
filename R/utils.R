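#' @import data.table
#' @importFrom stats rexp rbinom runif rnorm qchisq qnorm setNames
#' @importFrom utils head tail
NULL

# study window constants (calendar anchors of the enrolment design)
.study <- list(
  scan_start   = as.Date("2007-01-01"),  # episode scan lower bound
  enrol_start  = as.Date("2009-01-01"),  # cohort entry window
  enrol_end    = as.Date("2019-12-01"),
  study_end    = as.Date("2019-12-31"),  # administrative end of follow-up
  landmark_days = 30L,                   # post-discharge landmark period
  lookback_l04  = 180L,                  # pre-discharge immunosuppressant washout
  washout_days  = 730L,                  # pre-index transplant washout
  fu_cap_days   = 1826L,                 # 5 years of follow-up (365.25 * 5)
  days_per_year = 365.25
)

#' Round half up
#'
#' Rounds to `digits` decimal places with ties going away from zero, matching
#' the display convention of printed epidemiological tables (base `round()`
#' rounds half to even).
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage helper
#'
#' `num / den` expressed as a percentage, rounded half-up to one decimal --
#' the convention used throughout the descriptive tables (e.g. an organ's
#' share of the cohort, or a regimen's share of a backbone group).
#'
#' @param num numerator count
#' @param den denominator count
#' @param digits decimal places (default 1)
#' @return numeric percentage
#' @examples
#' pct(4029, 6914)  # 58.3
#' @export
pct <- function(num, den, digits = 1) {
  if (any(den == 0)) stop("pct(): zero denominator")
  round_half_up(100 * num / den, digits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_date <- function(x) as.Date(x, origin = "1970-01-01")

# deterministic child seed from a base seed and a stream label
# (double arithmetic: intermediate products can exceed .Machine$integer.max)
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 1009 + h %% 100003) %% 2147483587)
}
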