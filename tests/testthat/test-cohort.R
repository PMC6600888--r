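test_that("one seed fixes the whole cohort", {
  p <- cohort_params(n_participants = 60, seed = 3)
  expect_identical(generate_cohort(p), generate_cohort(p))
  p2 <- cohort_params(n_participants = 60, seed = 4)
  expect_false(identical(generate_cohort(p), generate_cohort(p2)))
})

test_that("strata proportions behave at the extremes", {
  all_drinkers <- generate_cohort(cohort_params(n_participants = 30,
                                                prop_non_drinker = 0, seed = 5))
  expect_true(all(vapply(all_drinkers,
                         function(p) !is.null(p$occasions), logical(1))))
  none <- generate_cohort(cohort_params(n_participants = 30,
                                        prop_non_drinker = 1, seed = 5))
  expect_true(all(vapply(none, function(p) is.null(p$occasions), logical(1))))
  # non-drinkers answer no to both gate questions and endorse no symptoms
  for (p in none) {
    expect_equal(drinker_status(p$prep_drank, p$check_drank), "non_drinker")
    expect_equal(dependence_status(p$dependence_ratings), "non_dependent")
  }
})

test_that("cohort records satisfy the structural invariants", {
  cohort <- generate_cohort(cohort_params(n_participants = 120, seed = 6))
  for (p in cohort) {
    if (is.null(p$occasions)) next
    occ <- p$occasions
    expect_lte(nrow(occ), 4)
    expect_false(is.unsorted(occ$days_before_survey))
    expect_true(occ$days_before_survey[1] <= 366)  # >=1 in-window occasion
    expect_true(all(occ$standard_drinks > 0))
    expect_equal(drinker_status(p$prep_drank, p$check_drank), "drinker")
  }
})

test_that("occasion timing follows the renewal process expectation", {
  set.seed(61)
  rate <- 2 / 30.4375  # twice a month
  counts <- vapply(1:40, function(i) {
    o <- generate_occasions(rate, log(17), 0.3)
    sum(o$days_before_survey <= 366)
  }, numeric(1))
  expect_gt(mean(counts), 24 * 0.5)
  expect_lt(mean(counts), 24 * 1.5)
  # degenerate quantity distribution
  o <- generate_occasions(rate, log(16), sigma_within = 0)
  expect_true(all(abs(o$standard_drinks - 16) < 1e-12))
  # a very rare drinker can have fewer than four occasions even past the window
  set.seed(62)
  o <- generate_occasions(1e-5, log(17), 0.3)
  expect_lte(nrow(o), 4)
})

test_that("reported categories bin the latent rates, with single-step noise", {
  set.seed(63)
  occ <- generate_occasions(2 / 30.4375, log(17), 0.3)
  rep0 <- report_categories(2 / 30.4375, occ, log(17), 0.3, noise_prob = 0)
  expect_equal(rep0$audit1m, "monthly_1_3")
  light_occ <- data.frame(occasion_rank = 1:4,
                          days_before_survey = c(10, 50, 90, 130),
                          standard_drinks = c(2, 3, 1, 4))
  rep_light <- report_categories(2 / 30.4375, light_occ, log(2), 0.1,
                                 noise_prob = 0)
  expect_equal(rep_light$audit3mv, "never")
  # full noise: report differs from truth by exactly one level
  for (i in 1:20) {
    repn <- report_categories(2 / 30.4375, occ, log(17), 0.3, noise_prob = 1)
    d1 <- abs(match(repn$audit1m, FREQUENCY_CATEGORIES) -
                match("monthly_1_3", FREQUENCY_CATEGORIES))
    expect_equal(d1, 1)
    expect_true(repn$audit1m != "never")
  }
})

test_that("the generated cohort reproduces the emulated study margins", {
  res <- calibration_scores()
  expect_gt(nrow(res), 3000)
  # frequency-class margins (multinomial by construction, so wide tolerance)
  a1 <- 100 * prop.table(table(factor(res$audit1m_score, 1:4)))
  expect_lt(max(abs(as.numeric(a1) - c(30.4, 42.4, 26.1, 1.1))), 2.5)
  # long-term risk share emerges from the latent rates and quantities
  expect_lt(abs(100 * mean(res$finnish_long) - 44), 5)
})
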