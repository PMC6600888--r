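#' Constants used throughout the package
#'
#' `ETHANOL_DENSITY` is the density of pure ethanol in g/mL (0.789),
#' `GRAMS_PER_STANDARD_DRINK` the ethanol mass of one Australian standard
#' drink (10 g), `DAYS_PER_MONTH` the average month length used to express
#' drinking frequency per month (365.25 / 12 = 30.4375), and
#' `SURVEY_WINDOW_DAYS` the past-year recall window (366 days).
#'
#' @name constants
#' @keywords internal
NULL

ETHANOL_DENSITY <- 0.789
GRAMS_PER_STANDARD_DRINK <- 10
DAYS_PER_MONTH <- 365.25 / 12
SURVEY_WINDOW_DAYS <- 366

stop_invalid <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_fraction <- function(x, field) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_invalid(field, "must be a fraction in [0, 1]")
  }
  x
}
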