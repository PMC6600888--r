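# Shared fixtures and independent oracles, all built in code.

test_catalog <- function() {
  data.frame(
    product_id = c("beer_can", "wine_bottle"),
    name = c("Full-strength beer can", "Bottled wine"),
    abv = c(0.048, 0.13),
    container_volume_ml = c(375, 750)
  )
}

# Independent Clopper-Pearson oracle: bisection on the exact binomial tail
# probabilities, no beta quantiles.
cp_oracle <- function(s, n, level = 0.95, tol = 1e-9) {
  alpha <- 1 - level
  bisect <- function(f, lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
      if (hi - lo < tol) break
    }
    (lo + hi) / 2
  }
  lower <- if (s == 0) 0 else {
    # largest p with P(X >= s | p) <= alpha/2
    bisect(function(p) sum(stats::dbinom(s:n, n, p)) - alpha / 2, 0, 1)
  }
  upper <- if (s == n) 1 else {
    # smallest p with P(X <= s | p) <= alpha/2
    bisect(function(p) alpha / 2 - sum(stats::dbinom(0:s, n, p)), 0, 1)
  }
  c(lower, upper)
}

# Brute-force shortened-Finnish estimates for one person: recomputes
# mean-quantity x frequency per day from first principles, sharing no code
# with the package implementation.
brute_force_estimates <- function(days, quantities) {
  out <- matrix(NA_real_, 4, 4)
  for (kq in 1:4) {
    for (kf in 1:4) {
      mq <- sum(quantities[1:kq]) / kq
      span <- days[kf]
      if (span < 1) span <- 1
      out[kq, kf] <- mq * kf / span
    }
  }
  out
}

manual_pearson_r <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Large-cohort scores used by several calibration checks; computed once.
.calib_env <- new.env(parent = emptyenv())
calibration_scores <- function() {
  if (is.null(.calib_env$scores)) {
    cohort <- generate_cohort(cohort_params(n_participants = 5000, seed = 7))
    drinkers <- Filter(function(p) !is.null(p$occasions), cohort)
    .calib_env$scores <- do.call(rbind, lapply(drinkers, function(p) {
      score_participant(p$sex, p$audit1m, p$audit3mv,
                        p$occasions$days_before_survey,
                        p$occasions$standard_drinks)
    }))
  }
  .calib_env$scores
}

# A six-person hand-checkable cohort: three clearly above every risk
# threshold, three clearly below all of them.
write_six_person_fixture <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  heavy_ids <- c("h1", "h2", "h3")
  light_ids <- c("l1", "l2", "l3")
  responses <- data.frame(
    person_id = c(heavy_ids, light_ids),
    sex = c("female", "male", "female", "male", "female", "male"),
    prep_drank = "yes", check_drank = "",
    audit1m = c(rep("weekly_1_3", 3), rep("lt_monthly", 3)),
    audit3mv = c(rep("most_days", 3), rep("never", 3)),
    dep1 = "never", dep2 = "never", dep3 = "never"
  )
  occ <- function(pid, drinks, days) {
    data.frame(person_id = pid, occasion_rank = 1:4,
               days_before_survey = days, standard_drinks = drinks)
  }
  occasions <- rbind(
    do.call(rbind, lapply(heavy_ids, occ, drinks = 20, days = c(5, 10, 15, 20))),
    do.call(rbind, lapply(light_ids, occ, drinks = 1, days = c(30, 60, 90, 120)))
  )
  write.csv(responses, file.path(dir, "responses.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(occasions, file.path(dir, "occasions.csv"), row.names = FALSE,
            quote = FALSE)
  dir
}
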