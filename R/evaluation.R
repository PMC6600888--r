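#' Cross-tabulate index-test flags against reference flags
#'
#' @param index_flags,reference_flags Equal-length logical vectors over the
#'   same drinkers.
#' @return List of counts `tp` (both positive), `fn` (reference positive
#'   only), `fp` (index positive only), `tn` (both negative).
#' @export
cross_tabulate <- function(index_flags, reference_flags) {
  if (length(index_flags) != length(reference_flags)) {
    stop_invalid("flags", "index and reference must have equal length")
  }
  if (anyNA(index_flags) || anyNA(reference_flags)) {
    stop_invalid("flags", "missing values are not allowed")
  }
  list(
    tp = sum(index_flags & reference_flags),
    fn = sum(!index_flags & reference_flags),
    fp = sum(index_flags & !reference_flags),
    tn = sum(!index_flags & !reference_flags)
  )
}

#' Reconstruct a 2x2 screening table from its printed marginals
#'
#' Given the number of participants, the reference-positive and
#' index-positive counts, and the total number of disagreements
#' (`fn + fp`), the four cells are determined uniquely:
#' `fp = (disagreements + index_positive - reference_positive) / 2`.
#'
#' @param n Total participants analysed.
#' @param reference_positive,index_positive Marginal positive counts.
#' @param disagreements Number of discordant classifications.
#' @return List with `tp`, `fn`, `fp`, `tn`.
#' @export
two_by_two_from_margins <- function(n, reference_positive, index_positive,
                                    disagreements) {
  fp2 <- disagreements + index_positive - reference_positive
  if (fp2 %% 2 != 0 || fp2 < 0 || fp2 / 2 > disagreements) {
    stop_invalid("marginals", "no 2x2 table is consistent with these counts")
  }
  fp <- fp2 / 2
  fn <- disagreements - fp
  tp <- reference_positive - fn
  tn <- n - tp - fn - fp
  if (min(tp, tn) < 0) {
    stop_invalid("marginals", "no 2x2 table is consistent with these counts")
  }
  list(tp = tp, fn = fn, fp = fp, tn = tn)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Bounds from beta quantiles: lower `qbeta(a/2, s, n - s + 1)` (0 when
#' `s = 0`), upper `qbeta(1 - a/2, s + 1, n - s)` (1 when `s = n`). Exact
#' intervals are conservative: realised coverage is at least the nominal
#' level.
#'
#' @param successes,n Binomial counts, `0 <= successes <= n`, `n >= 1`.
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(lower, upper)`.
#' @export
clopper_pearson <- function(successes, n, level = 0.95) {
  if (n < 1 || successes < 0 || successes > n ||
      successes != as.integer(successes) || n != as.integer(n)) {
    stop_invalid("counts", "need integer 0 <= successes <= n, n >= 1")
  }
  if (level <= 0 || level >= 1) {
    stop_invalid("level", "must be in (0, 1)")
  }
  alpha <- 1 - level
  lower <- if (successes == 0) 0 else stats::qbeta(alpha / 2, successes, n - successes + 1)
  upper <- if (successes == n) 1 else stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(lower = lower, upper = upper)
}

#' Sensitivity and specificity with exact confidence intervals
#'
#' @param tab A 2x2 list as from [cross_tabulate()].
#' @param level Confidence level for the Clopper-Pearson intervals.
#' @return List with `sensitivity`, `specificity`, `ci_sensitivity`,
#'   `ci_specificity`, and the input counts.
#' @export
sensitivity_specificity <- function(tab, level = 0.95) {
  with(tab, {
    if (tp + fn < 1) stop("no reference-positive participants: sensitivity undefined",
                          call. = FALSE)
    if (fp + tn < 1) stop("no reference-negative participants: specificity undefined",
                          call. = FALSE)
    list(
      tp = tp, fn = fn, fp = fp, tn = tn,
      n = tp + fn + fp + tn,
      sensitivity = tp / (tp + fn),
      specificity = tn / (fp + tn),
      ci_sensitivity = clopper_pearson(tp, tp + fn, level),
      ci_specificity = clopper_pearson(tn, fp + tn, level)
    )
  })
}

#' Pearson product-moment correlation with validation
#'
#' @param x,y Equal-length numeric vectors (length >= 3) with nonzero
#'   variance.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop_invalid("x, y", "equal length >= 3 required")
  }
  if (anyNA(x) || anyNA(y)) {
    stop_invalid("x, y", "missing values are not allowed")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  stats::cor(x, y, method = "pearson")
}

#' Variance retained by shortened Finnish-method variants
#'
#' For each combination of `k_quantity` and `k_frequency` in 1..4, computes
#' each drinker's shortened consumption estimate and the squared Pearson
#' correlation (r^2, proportion of variance retained) against the full
#' four-occasion estimate. Only drinkers with at least four in-window
#' occasions enter; the count excluded is returned.
#'
#' @param occasions Data frame in the drinks dialect: `person_id`,
#'   `occasion_rank` (1 = most recent), `days_before_survey`,
#'   `standard_drinks`.
#' @param variable `"avg_drinks_per_day"` (default, combining both axes) or
#'   `"drinks_per_occasion"` (quantity component only, constant across the
#'   frequency axis).
#' @param window_days Recall window in days.
#' @return List with `grid` (4x4 matrix of r^2, rows = k_quantity, cols =
#'   k_frequency), `n_used`, `n_excluded`.
#' @export
retention_grid <- function(occasions,
                           variable = c("avg_drinks_per_day",
                                        "drinks_per_occasion"),
                           window_days = SURVEY_WINDOW_DAYS) {
  variable <- match.arg(variable)
  est <- shortened_estimates(occasions, variable, window_days)
  if (est$n_used < 3) {
    stop("fewer than 3 drinkers with four in-window occasions: retention grid undefined",
         call. = FALSE)
  }
  full <- est$values[, "4_4"]
  grid <- matrix(NA_real_, 4, 4,
                 dimnames = list(k_quantity = 1:4, k_frequency = 1:4))
  for (kq in 1:4) {
    for (kf in 1:4) {
      grid[kq, kf] <- pearson_r(est$values[, paste(kq, kf, sep = "_")], full)^2
    }
  }
  grid[4, 4] <- 1  # correlation of the full estimate with itself
  list(grid = grid, n_used = est$n_used, n_excluded = est$n_excluded)
}

# Per-person shortened estimates for every (k_quantity, k_frequency) pair.
shortened_estimates <- function(occasions, variable, window_days) {
  by_person <- split(occasions, occasions$person_id)
  rows <- lapply(by_person, function(d) {
    d <- d[order(d$occasion_rank), ]
    w <- filter_window(d$days_before_survey, d$standard_drinks, window_days)
    if (length(w$days) < 4) {
      return(NULL)
    }
    vals <- numeric(16)
    nm <- character(16)
    i <- 1
    for (kq in 1:4) {
      for (kf in 1:4) {
        vals[i] <- if (variable == "avg_drinks_per_day") {
          average_drinks_per_day(w$days, w$quantities, kq, kf)
        } else {
          drinks_per_occasion(w$quantities, kq)
        }
        nm[i] <- paste(kq, kf, sep = "_")
        i <- i + 1
      }
    }
    stats::setNames(vals, nm)
  })
  keep <- !vapply(rows, is.null, logical(1))
  values <- do.call(rbind, rows[keep])
  list(values = values, n_used = sum(keep), n_excluded = sum(!keep))
}

#' Drop drinkers with zero variation across their occasion quantities
#'
#' Sensitivity analysis for the retention grid: removes drinkers whose four
#' most recent in-window quantities are all equal (to within `tol`), since
#' their shortened quantity estimates are trivially identical to the full
#' one.
#'
#' @param occasions Drinks-dialect occasions data frame.
#' @param tol Equality tolerance in standard drinks.
#' @param window_days Recall window in days.
#' @return List with `occasions` (filtered) and `n_dropped`.
#' @export
exclude_zero_variance <- function(occasions, tol = 1e-9,
                                  window_days = SURVEY_WINDOW_DAYS) {
  if (nrow(occasions) == 0) {
    return(list(occasions = occasions, n_dropped = 0L))
  }
  by_person <- split(occasions, occasions$person_id)
  constant <- vapply(by_person, function(d) {
    d <- d[order(d$occasion_rank), ]
    w <- filter_window(d$days_before_survey, d$standard_drinks, window_days)
    if (length(w$quantities) < 4) {
      return(FALSE)  # handled by the retention grid's own exclusion
    }
    q <- w$quantities[1:4]
    diff(range(q)) <= tol
  }, logical(1))
  drop_ids <- names(by_person)[constant]
  list(
    occasions = occasions[!occasions$person_id %in% drop_ids, , drop = FALSE],
    n_dropped = length(drop_ids)
  )
}
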