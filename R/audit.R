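#' AUDIT-Cm frequency categories
#'
#' The modified AUDIT-C frequency items (AUDIT-1m, AUDIT-3mV) use a
#' five-level colloquial scale. Tokens, in score order 0-4:
#' `never`, `lt_monthly` ("once in a blue moon"), `monthly_1_3`
#' ("sometimes, 1-3 times a month"), `weekly_1_3` ("a few times a week"),
#' `most_days` ("most days or every day").
#'
#' @export
FREQUENCY_CATEGORIES <- c("never", "lt_monthly", "monthly_1_3",
                          "weekly_1_3", "most_days")

#' Convert a drinking rate to occasions per day
#'
#' The unit conversion behind the category-midpoint table: a rate of `n`
#' occasions per period becomes `n / period_days` occasions per day, so
#' once-weekly drinking is 1/7 = 0.14 occasions/day at two decimals.
#'
#' @param n Occasions per period.
#' @param period_days Length of the period in days: 7 for weekly rates,
#'   30.4375 (the average month) for monthly rates.
#' @return Occasions per day.
#' @examples
#' occasions_per_day(1, 7) # weekly drinking, 0.1428...
#' @export
occasions_per_day <- function(n, period_days) {
  if (any(!is.finite(n)) || any(n < 0)) stop_invalid("n", "must be >= 0")
  if (any(!is.finite(period_days)) || any(period_days <= 0)) {
    stop_invalid("period_days", "must be > 0")
  }
  n / period_days
}

#' Default category midpoints, as occasions per day
#'
#' The midpoint of each frequency response category, converted to occasions
#' per day with [occasions_per_day()]: `never` 0; `lt_monthly` 0.5
#' occasions/month; `monthly_1_3` 2/month; `weekly_1_3` 2/week;
#' `most_days` 5.5/week (midpoint of 4-7 days a week).
#'
#' @export
DEFAULT_FREQUENCY_MIDPOINTS <- c(
  never       = 0,
  lt_monthly  = occasions_per_day(0.5, DAYS_PER_MONTH),
  monthly_1_3 = occasions_per_day(2, DAYS_PER_MONTH),
  weekly_1_3  = occasions_per_day(2, 7),
  most_days   = occasions_per_day(5.5, 7)
)

#' Midpoints of the AUDIT-2m quantity categories, in standard drinks
#'
#' Categories 1-2, 3-4, 5-6, 7-9 take their midpoints; the unbounded top
#' category (10+) is assigned 10 standard drinks.
#'
#' @export
AUDIT2M_QUANTITY_MIDPOINTS <- c(1.5, 3.5, 5.5, 8, 10)

check_category <- function(category, field = "category") {
  if (length(category) != 1 || is.na(category) ||
      !category %in% FREQUENCY_CATEGORIES) {
    stop_invalid(field, sprintf("must be one of: %s",
                                paste(FREQUENCY_CATEGORIES, collapse = ", ")))
  }
  category
}

round_half_up <- function(x) floor(x + 0.5)

#' Score a frequency category at its ordinal position
#'
#' `never` scores 0 through `most_days` scoring 4. AUDIT-1m is only asked of
#' confirmed past-year drinkers, so its questionnaire offers no `never`
#' option; supplying it is a data error.
#'
#' @param category A frequency category token.
#' @return Item score 0-4.
#' @export
score_audit1m <- function(category) {
  check_category(category, "audit1m")
  if (category == "never") {
    stop_invalid("audit1m", "'never' is not offered to past-year drinkers")
  }
  match(category, FREQUENCY_CATEGORIES) - 1L
}

#' @rdname score_audit1m
#' @export
score_audit3mv <- function(category) {
  check_category(category, "audit3mv")
  match(category, FREQUENCY_CATEGORIES) - 1L
}

#' Derive the AUDIT-2m item score from usual quantity
#'
#' The continuous usual-quantity estimate (mean standard drinks per occasion
#' from the last four occasions) is recoded into the five AUDIT-2 response
#' categories: 1-2 drinks scores 0; 3-4 scores 1; 5-6 scores 2; 7-9 scores 3;
#' 10 or more scores 4. Because the printed categories are integer drink
#' counts, a continuous value is first rounded half-up to an integer (so 4.5
#' rounds to 5 and lands in the 5-6 category).
#'
#' @param usual_drinks_per_occasion Mean standard drinks per occasion (>= 0).
#' @return Item score 0-4 (vectorised).
#' @export
derive_audit2m <- function(usual_drinks_per_occasion) {
  x <- usual_drinks_per_occasion
  if (any(!is.finite(x)) || any(x < 0)) {
    stop_invalid("usual_drinks_per_occasion", "must be >= 0")
  }
  d <- round_half_up(x)
  score <- ifelse(d <= 2, 0L,
           ifelse(d <= 4, 1L,
           ifelse(d <= 6, 2L,
           ifelse(d <= 9, 3L, 4L))))
  as.integer(score)
}

#' Total AUDIT-Cm score with sex-specific risk threshold
#'
#' Sums the three modified item scores and flags at-risk drinking at a total
#' of 3 or more for women and 4 or more for men (the thresholds recommended
#' for Australian Aboriginal community-controlled health services).
#'
#' @param audit1m_score,audit2m_score,audit3mv_score Item scores, each 0-4.
#' @param sex `"female"` or `"male"`.
#' @param thresholds Named numeric vector of at-risk cut-offs per sex.
#' @return List with `total` (0-12) and `at_risk` (logical).
#' @export
total_audit_cm <- function(audit1m_score, audit2m_score, audit3mv_score, sex,
                           thresholds = c(female = 3, male = 4)) {
  scores <- c(audit1m_score, audit2m_score, audit3mv_score)
  if (length(scores) != 3 || any(is.na(scores)) ||
      any(scores < 0) || any(scores > 4)) {
    stop_invalid("item scores", "three scores each in 0-4 are required")
  }
  if (length(sex) != 1 || !sex %in% names(thresholds)) {
    stop_invalid("sex", sprintf("must be one of: %s",
                                paste(names(thresholds), collapse = ", ")))
  }
  total <- sum(scores)
  list(total = total, at_risk = total >= thresholds[[sex]])
}

#' Midpoint frequency of a response category, per day
#'
#' @param category A frequency category token.
#' @param midpoints Named midpoint table (occasions/day); defaults to
#'   [DEFAULT_FREQUENCY_MIDPOINTS].
#' @return Occasions per day.
#' @export
frequency_midpoint_per_day <- function(category,
                                       midpoints = DEFAULT_FREQUENCY_MIDPOINTS) {
  check_category(category)
  midpoints[[category]]
}

#' Midpoint quantity of an AUDIT-2m score, in standard drinks
#'
#' @param audit2m_score Item score 0-4.
#' @return Standard drinks (1.5, 3.5, 5.5, 8 or 10).
#' @export
quantity_midpoint <- function(audit2m_score) {
  if (length(audit2m_score) != 1 || is.na(audit2m_score) ||
      audit2m_score < 0 || audit2m_score > 4 ||
      audit2m_score != as.integer(audit2m_score)) {
    stop_invalid("audit2m_score", "must be an integer 0-4")
  }
  AUDIT2M_QUANTITY_MIDPOINTS[audit2m_score + 1L]
}

risk_status <- function(method, short_term, long_term) {
  list(method = method, short_term = short_term, long_term = long_term,
       any_risk = short_term || long_term)
}

#' Risk classification from AUDIT-1m plus AUDIT-2m
#'
#' Short-term risk: the usual quantity midpoint exceeds 4 standard drinks
#' (AUDIT-2m score >= 2) and the participant drank in the past year. With
#' `short_term_min_frequency = "monthly"` the frequency condition tightens to
#' drinking at least monthly (AUDIT-1m category `monthly_1_3` or above).
#' Long-term risk: the midpoint frequency (occasions/day) times the midpoint
#' quantity exceeds 2 standard drinks per day.
#'
#' @param audit1m_category Frequency category token (not `never`).
#' @param audit2m_score AUDIT-2m item score 0-4.
#' @param is_past_year_drinker Logical, from the drinker gate.
#' @param short_term_min_frequency `"past_year"` (default) or `"monthly"`.
#' @param midpoints Frequency midpoint table (occasions/day).
#' @return A risk-status list (`method = "audit_12"`).
#' @export
audit12_risk <- function(audit1m_category, audit2m_score,
                         is_past_year_drinker = TRUE,
                         short_term_min_frequency = c("past_year", "monthly"),
                         midpoints = DEFAULT_FREQUENCY_MIDPOINTS) {
  short_term_min_frequency <- match.arg(short_term_min_frequency)
  score_audit1m(audit1m_category)  # validates, incl. the no-'never' rule
  q_mid <- quantity_midpoint(audit2m_score)
  f_mid <- frequency_midpoint_per_day(audit1m_category, midpoints)
  freq_ok <- if (short_term_min_frequency == "past_year") {
    isTRUE(is_past_year_drinker)
  } else {
    match(audit1m_category, FREQUENCY_CATEGORIES) >= 3L  # monthly_1_3+
  }
  risk_status("audit_12",
              short_term = q_mid > 4 && freq_ok,
              long_term = f_mid * q_mid > 2)
}

#' Risk classification from AUDIT-3mV alone
#'
#' AUDIT-3mV asks how often the respondent drinks five or more standard
#' drinks in a day. Any non-`never` response implies short-term risk at some
#' frequency; long-term risk multiplies 5 standard drinks by the midpoint
#' frequency of the selected category and tests against 2 drinks/day.
#'
#' @param audit3mv_category Frequency category token.
#' @inheritParams audit12_risk
#' @return A risk-status list (`method = "audit_3"`).
#' @export
audit3_risk <- function(audit3mv_category,
                        midpoints = DEFAULT_FREQUENCY_MIDPOINTS) {
  check_category(audit3mv_category, "audit3mv")
  f_mid <- frequency_midpoint_per_day(audit3mv_category, midpoints)
  risk_status("audit_3",
              short_term = audit3mv_category != "never",
              long_term = 5 * f_mid > 2)
}
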