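#' @importFrom rlang %||% .data abort warn inform
#' @importFrom tibble tibble as_tibble
NULL

# Reporting convention: decimal rounding with halves away from zero, so a
# prevalence of 0.1855 prints as 18.6 regardless of the platform's banker's
# rounding.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Report a ratio as a percentage at the conventional printed precision
#'
#' Percentages are reported to one decimal place with halves rounded away
#' from zero, the convention used throughout the package's summary tables.
#'
#' @param numerator,denominator Numeric scalars or vectors.
#' @param digits Decimal places (default 1).
#' @return Numeric percentage(s).
#' @export
#' @examples
#' percent_of(327800, 358889) # 91.3
percent_of <- function(numerator, denominator, digits = 1) {
  round_half_up(100 * numerator / denominator, digits)
}

#' Report a mean annual rate at the conventional printed precision
#'
#' @param total Total event count.
#' @param n Number of patients.
#' @return Rate per patient per year, to one decimal place.
#' @export
#' @examples
#' rate_per_patient(932023, 61042) # 15.3
rate_per_patient <- function(total, n) {
  round_half_up(total / n, 1)
}

# Deterministic per-stage seeds derived from one root seed, kept within the
# 32-bit integer range R requires.
derive_seed <- function(root_seed, stage) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1)
  offsets <- c(
    simulate = 11L, cohort = 23L, registers = 37L,
    utilisation = 53L, inequalities = 71L, pipeline = 97L
  )
  off <- offsets[[stage]]
  as.integer((as.numeric(root_seed) * 1009 + off * 9973) %% 2147483647)
}

assert_scalar_date <- function(x, what) {
  if (!inherits(x, "Date") || length(x) != 1 || is.na(x)) {
    abort(paste0("`", what, "` must be a single non-missing Date"))
  }
  invisible(x)
}

# 12-month analysis window ending at the extraction date, as a half-open
# interval (extraction_date - 365, extraction_date].
analysis_window <- function(extraction_date, days = 365L) {
  assert_scalar_date(extraction_date, "extraction_date")
  list(start_exclusive = extraction_date - days, end_inclusive = extraction_date)
}

in_window <- function(dates, window) {
  dates > window$start_exclusive & dates <= window$end_inclusive
}
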