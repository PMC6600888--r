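test_that("cross-tabulation counts the four cells by enumeration", {
  t <- cross_tabulate(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
  expect_equal(t, list(tp = 1L, fn = 0L, fp = 1L, tn = 1L))
  flags <- c(TRUE, FALSE, TRUE, TRUE)
  t <- cross_tabulate(flags, flags)
  expect_equal(t$fn + t$fp, 0L)
  t <- cross_tabulate(rep(TRUE, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(t$tn, 0L)
  expect_error(cross_tabulate(TRUE, c(TRUE, FALSE)), "equal length")
})

test_that("sensitivity and specificity are invariant to participant order", {
  set.seed(51)
  index <- runif(50) < 0.6
  ref <- runif(50) < 0.5
  a <- sensitivity_specificity(cross_tabulate(index, ref))
  p <- sample(50)
  b <- sensitivity_specificity(cross_tabulate(index[p], ref[p]))
  expect_equal(a, b)
})

test_that("the unique 2x2 table is recovered from screening marginals", {
  t <- two_by_two_from_margins(184, 175, 177, 4)
  expect_equal(t, list(tp = 174, fn = 1, fp = 3, tn = 6))
  expect_equal(two_by_two_from_margins(10, 8, 9, 1),
               list(tp = 8, fn = 0, fp = 1, tn = 1))
  expect_error(two_by_two_from_margins(10, 8, 9, 2), "consistent")  # odd split
  expect_error(two_by_two_from_margins(10, 3, 8, 3), "consistent")
})

test_that("exact intervals match a binomial-tail bisection oracle", {
  for (n in 1:30) {
    for (s in 0:n) {
      got <- clopper_pearson(s, n)
      want <- cp_oracle(s, n)
      expect_equal(unname(got), want, tolerance = 1e-6)
    }
  }
  # and base R's binom.test, which uses the same exact construction
  for (case in list(c(6, 9), c(174, 175), c(3, 28))) {
    expect_equal(unname(clopper_pearson(case[1], case[2])),
                 as.numeric(binom.test(case[1], case[2])$conf.int),
                 tolerance = 1e-12)
  }
  expect_equal(clopper_pearson(0, 10)[["lower"]], 0)
  expect_equal(clopper_pearson(10, 10)[["upper"]], 1)
  expect_error(clopper_pearson(5, 4), "counts")
})

test_that("exact intervals are conservative: coverage at least nominal", {
  set.seed(52)
  draws <- rbinom(2000, 9, 0.7)
  covered <- vapply(draws, function(s) {
    ci <- clopper_pearson(s, 9)
    ci[1] <= 0.7 && 0.7 <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.93)
})

test_that("screening accuracy summarises a 2x2 with exact intervals", {
  r <- sensitivity_specificity(list(tp = 174, fn = 1, fp = 3, tn = 6))
  expect_equal(r$sensitivity, 174 / 175)
  expect_equal(r$specificity, 6 / 9)
  expect_true(r$ci_sensitivity[1] <= r$sensitivity &&
              r$sensitivity <= r$ci_sensitivity[2])
  perfect <- sensitivity_specificity(list(tp = 5, fn = 0, fp = 0, tn = 5))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  none <- sensitivity_specificity(list(tp = 0, fn = 5, fp = 0, tn = 5))
  expect_equal(none$sensitivity, 0)
  expect_equal(none$specificity, 1)
  expect_error(sensitivity_specificity(list(tp = 0, fn = 0, fp = 2, tn = 2)),
               "sensitivity undefined")
})

test_that("pearson_r is the product-moment correlation", {
  x <- c(2, 5, 9, 11)
  expect_equal(pearson_r(x, x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 4)), 0.982, tolerance = 0.001)
  expect_equal(pearson_r(c(1, 2, 3), c(1, 2, 4)),
               manual_pearson_r(c(1, 2, 3), c(1, 2, 4)))
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "length")
})

make_retention_cohort <- function(n, seed) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(person_id = sprintf("p%03d", i), occasion_rank = 1:4,
               days_before_survey = sort(runif(4, 1, 350)),
               standard_drinks = rlnorm(4, log(15), 0.8))
  }))
}

test_that("retention grid matches an independent brute-force recomputation", {
  occ <- make_retention_cohort(200, seed = 53)
  ret <- retention_grid(occ)
  expect_equal(ret$n_used, 200)
  expect_identical(ret$grid[4, 4], 1)
  expect_true(all(ret$grid >= 0 & ret$grid <= 1))

  # oracle: recompute every estimate and correlation from first principles
  ests <- lapply(split(occ, occ$person_id), function(d) {
    d <- d[order(d$occasion_rank), ]
    brute_force_estimates(d$days_before_survey, d$standard_drinks)
  })
  for (kq in 1:4) {
    for (kf in 1:4) {
      short <- vapply(ests, function(e) e[kq, kf], numeric(1))
      full <- vapply(ests, function(e) e[4, 4], numeric(1))
      expect_equal(ret$grid[kq, kf], manual_pearson_r(short, full)^2,
                   tolerance = 1e-12)
    }
  }
})

test_that("identical quantities on evenly spaced days retain all variance", {
  occ <- do.call(rbind, lapply(1:10, function(i) {
    data.frame(person_id = sprintf("p%02d", i), occasion_rank = 1:4,
               days_before_survey = i * c(10, 20, 30, 40),
               standard_drinks = rep(c(2, 25, 7, 13, 18, 4, 30, 9, 11, 21)[i], 4))
  }))
  ret <- retention_grid(occ)
  expect_equal(unname(ret$grid), matrix(1, 4, 4), tolerance = 1e-12)
})

test_that("drinkers with under four in-window occasions are excluded and counted", {
  occ <- make_retention_cohort(10, seed = 54)
  few <- data.frame(person_id = "few1", occasion_rank = 1:3,
                    days_before_survey = c(5, 10, 15), standard_drinks = 8)
  old <- data.frame(person_id = "old1", occasion_rank = 1:4,
                    days_before_survey = c(5, 10, 15, 400), standard_drinks = 8)
  ret <- retention_grid(rbind(occ, few, old))
  expect_equal(ret$n_used, 10)
  expect_equal(ret$n_excluded, 2)
  expect_error(retention_grid(occ[occ$person_id %in% c("p001", "p002"), ]),
               "fewer than 3")
})

test_that("zero-variance drinkers are dropped for the sensitivity analysis", {
  occ <- make_retention_cohort(5, seed = 55)
  const <- data.frame(person_id = "const1", occasion_rank = 1:4,
                      days_before_survey = c(3, 9, 27, 81),
                      standard_drinks = 12)
  near <- data.frame(person_id = "near1", occasion_rank = 1:4,
                     days_before_survey = c(3, 9, 27, 81),
                     standard_drinks = c(12, 12, 12, 11))
  res <- exclude_zero_variance(rbind(occ, const, near))
  expect_equal(res$n_dropped, 1)
  expect_false("const1" %in% res$occasions$person_id)
  expect_true("near1" %in% res$occasions$person_id)
  empty <- exclude_zero_variance(occ[0, ])
  expect_equal(empty$n_dropped, 0L)
  expect_equal(nrow(empty$occasions), 0L)
})
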