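#' Finnish-method consumption estimation
#'
#' The Finnish method asks about the timing and quantity of the last (up to)
#' four drinking occasions and derives: drinking frequency (occasions per
#' month), usual quantity (standard drinks per occasion), average consumption
#' (standard drinks per day), and the largest single-occasion quantity.
#' Shortened variants use only the most recent `k` occasions for the quantity
#' and/or frequency components.
#'
#' Frequency estimator: with occasions ordered most-recent-first and the k-th
#' most recent occasion `span` days before the survey, frequency is
#' `k / max(span, 1) * 30.4375` occasions per month (the clamp avoids
#' division by zero when the k-th occasion was on the survey day).
#'
#' @name finnish_method
NULL

check_sorted_days <- function(days) {
  if (length(days) == 0) {
    stop("no drinking occasions: frequency undefined (treat as non-drinker)",
         call. = FALSE)
  }
  if (any(!is.finite(days)) || any(days < 0)) {
    stop_invalid("days_before_survey", "must be non-negative")
  }
  if (is.unsorted(days)) {
    stop_invalid("occasions", "must be sorted most-recent-first")
  }
  days
}

#' Drinking frequency from occasion timing
#'
#' @param days Days before survey for each occasion, most recent first.
#' @param k_frequency Number of most recent occasions to use (1-4).
#' @return Occasions per month.
#' @examples
#' drinking_frequency(c(7, 14, 21, 28), 4) # 4/28 * 30.4375
#' @export
drinking_frequency <- function(days, k_frequency = 4L) {
  check_sorted_days(days)
  if (k_frequency < 1 || k_frequency > length(days)) {
    stop_invalid("k_frequency", "must be between 1 and the number of occasions")
  }
  span <- max(days[k_frequency], 1)
  k_frequency / span * DAYS_PER_MONTH
}

#' Usual quantity: mean standard drinks over the k most recent occasions
#'
#' @param quantities Standard drinks per occasion, most recent first.
#' @param k_quantity Number of most recent occasions to average (1-4).
#' @return Mean standard drinks per drinking occasion.
#' @export
drinks_per_occasion <- function(quantities, k_quantity = 4L) {
  if (length(quantities) == 0) {
    stop("no drinking occasions: quantity undefined", call. = FALSE)
  }
  if (any(!is.finite(quantities)) || any(quantities < 0)) {
    stop_invalid("quantities", "must be >= 0")
  }
  if (k_quantity < 1 || k_quantity > length(quantities)) {
    stop_invalid("k_quantity", "must be between 1 and the number of occasions")
  }
  mean(quantities[seq_len(k_quantity)])
}

#' Average standard drinks per day
#'
#' The product of usual quantity and drinking frequency, expressed per day:
#' `drinks_per_occasion * drinking_frequency / DAYS_PER_MONTH`.
#'
#' @inheritParams drinking_frequency
#' @inheritParams drinks_per_occasion
#' @return Standard drinks per day.
#' @export
average_drinks_per_day <- function(days, quantities, k_quantity = 4L,
                                   k_frequency = 4L) {
  drinks_per_occasion(quantities, k_quantity) *
    drinking_frequency(days, k_frequency) / DAYS_PER_MONTH
}

#' Maximum standard drinks on any recorded occasion
#'
#' @param quantities Standard drinks per occasion.
#' @return Largest single-occasion quantity.
#' @export
max_drinks_single_occasion <- function(quantities) {
  if (length(quantities) == 0) {
    stop("no drinking occasions: maximum undefined", call. = FALSE)
  }
  if (any(!is.finite(quantities)) || any(quantities < 0)) {
    stop_invalid("quantities", "must be >= 0")
  }
  max(quantities)
}

#' Restrict occasions to the past-year recall window
#'
#' Occasions more than `window_days` days before the survey fall outside the
#' "last 12 months" recall period and are dropped before any Finnish-method
#' computation. A person left with zero in-window occasions is treated as a
#' past-year non-drinker by callers.
#'
#' @param days,quantities Parallel vectors, most recent first.
#' @param window_days Recall window in days (default 366).
#' @return List with in-window `days` and `quantities`.
#' @export
filter_window <- function(days, quantities, window_days = SURVEY_WINDOW_DAYS) {
  keep <- days <= window_days
  list(days = days[keep], quantities = quantities[keep])
}

#' Finnish-method consumption summary for one person
#'
#' Applies the recall window, then computes the four Finnish-method
#' estimates using the `k` most recent occasions for each component
#' (both capped at the number of in-window occasions available).
#'
#' @param days,quantities Parallel vectors, most recent first.
#' @param k_quantity,k_frequency Occasions used for the quantity and
#'   frequency components (defaults 4).
#' @param window_days Recall window in days.
#' @return A one-row data frame with `n_occasions`, `k_quantity`,
#'   `k_frequency`, `freq_per_month`, `drinks_per_occasion`,
#'   `avg_drinks_per_day`, `max_single_occasion`; or `NULL` when no occasion
#'   falls inside the window.
#' @export
consumption_summary <- function(days, quantities, k_quantity = 4L,
                                k_frequency = 4L,
                                window_days = SURVEY_WINDOW_DAYS) {
  w <- filter_window(days, quantities, window_days)
  n <- length(w$days)
  if (n == 0) {
    return(NULL)
  }
  check_sorted_days(w$days)
  kq <- min(k_quantity, n)
  kf <- min(k_frequency, n)
  data.frame(
    n_occasions = n,
    k_quantity = kq,
    k_frequency = kf,
    freq_per_month = drinking_frequency(w$days, kf),
    drinks_per_occasion = drinks_per_occasion(w$quantities, kq),
    avg_drinks_per_day = average_drinks_per_day(w$days, w$quantities, kq, kf),
    max_single_occasion = max_drinks_single_occasion(w$quantities)
  )
}
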