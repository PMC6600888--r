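test_that("AUDIT-2m recodes usual quantity into the five categories", {
  expect_identical(derive_audit2m(12), 4L)
  expect_identical(derive_audit2m(1), 0L)
  expect_identical(derive_audit2m(4.5), 2L)  # rounds half-up to 5 -> '5-6'
  expect_identical(derive_audit2m(c(2, 3, 5, 7, 10)), c(0L, 1L, 2L, 3L, 4L))
  expect_identical(derive_audit2m(c(2.4, 2.5)), c(0L, 1L))
  expect_error(derive_audit2m(-1), "usual_drinks_per_occasion")
})

test_that("AUDIT-2m recoding is a non-decreasing step function onto 0..4", {
  grid <- seq(0, 20, by = 0.1)
  scores <- derive_audit2m(grid)
  expect_true(all(diff(scores) >= 0))
  expect_identical(sort(unique(scores)), 0:4)
})

test_that("frequency items score at their ordinal position", {
  expect_identical(score_audit1m("monthly_1_3"), 2L)
  expect_identical(score_audit1m("most_days"), 4L)
  expect_identical(score_audit3mv("never"), 0L)
  expect_identical(score_audit3mv("most_days"), 4L)
  expect_error(score_audit1m("never"), "never")
  expect_error(score_audit3mv("Weekly"), "must be one of")
})

test_that("AUDIT-Cm total applies sex-specific thresholds", {
  r <- total_audit_cm(1, 4, 2, "male")
  expect_equal(r$total, 7)
  expect_true(r$at_risk)
  expect_false(total_audit_cm(1, 1, 0, "female")$at_risk)
  expect_true(total_audit_cm(1, 1, 1, "female")$at_risk)   # 3 >= 3
  expect_false(total_audit_cm(1, 1, 1, "male")$at_risk)    # 3 < 4
  expect_error(total_audit_cm(1, NA, 1, "male"), "item scores")
  expect_error(total_audit_cm(1, 1, 1, "other"), "sex")
})

test_that("raising an item never lowers the total or clears at-risk", {
  for (sex in c("female", "male")) {
    for (a in 0:3) for (b in 0:3) for (c in 0:3) {
      lo <- total_audit_cm(a, b, c, sex)
      for (bump in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
        hi <- total_audit_cm(a + bump[1], b + bump[2], c + bump[3], sex)
        expect_gte(hi$total, lo$total)
        expect_true(hi$at_risk >= lo$at_risk)
      }
    }
  }
})

test_that("category midpoints convert to occasions per day", {
  expect_equal(round(occasions_per_day(1, 7), 2), 0.14)  # weekly drinking
  expect_equal(frequency_midpoint_per_day("never"), 0)
  expect_equal(frequency_midpoint_per_day("lt_monthly"), 0.5 / 30.4375)
  expect_equal(frequency_midpoint_per_day("weekly_1_3"), 2 / 7)
  expect_equal(round(frequency_midpoint_per_day("weekly_1_3"), 4), 0.2857)
  expect_error(frequency_midpoint_per_day("daily"), "must be one of")
})

test_that("quantity midpoints use 10 drinks for the open top category", {
  expect_equal(vapply(0:4, quantity_midpoint, numeric(1)),
               c(1.5, 3.5, 5.5, 8, 10))
  expect_error(quantity_midpoint(5), "audit2m_score")
  expect_error(quantity_midpoint(1.5), "audit2m_score")
})

test_that("AUDIT-1m+2m risk combines midpoint frequency and quantity", {
  r <- audit12_risk("weekly_1_3", 4)
  expect_true(r$short_term)
  expect_true(r$long_term)     # 2/7 * 10 = 2.857 > 2
  r <- audit12_risk("lt_monthly", 4)
  expect_true(r$short_term)
  expect_false(r$long_term)    # 0.0164 * 10 = 0.164
  r <- audit12_risk("most_days", 0)
  expect_false(r$short_term)   # midpoint 1.5 <= 4
  expect_false(r$long_term)    # 0.786 * 1.5 = 1.18
  expect_equal(r$any_risk, r$short_term || r$long_term)
})

test_that("the monthly short-term variant tightens the frequency gate", {
  expect_true(audit12_risk("lt_monthly", 4,
                           short_term_min_frequency = "past_year")$short_term)
  expect_false(audit12_risk("lt_monthly", 4,
                            short_term_min_frequency = "monthly")$short_term)
  expect_true(audit12_risk("monthly_1_3", 4,
                           short_term_min_frequency = "monthly")$short_term)
})

test_that("AUDIT-3mV risk: any heavy drinking is short-term risk", {
  expect_false(audit3_risk("never")$short_term)
  expect_false(audit3_risk("never")$long_term)
  r <- audit3_risk("weekly_1_3")
  expect_true(r$short_term)
  expect_false(r$long_term)    # 5 * 2/7 = 1.43 <= 2
  r <- audit3_risk("most_days")
  expect_true(r$short_term)
  expect_true(r$long_term)     # 5 * 5.5/7 = 3.93 > 2
})

test_that("under default midpoints AUDIT-3mV long-term risk is exactly 'most days'", {
  for (cat in FREQUENCY_CATEGORIES) {
    expect_identical(audit3_risk(cat)$long_term, cat == "most_days")
  }
})

test_that("raising a frequency category never lowers a risk flag", {
  for (i in 2:4) {
    lo1 <- audit12_risk(FREQUENCY_CATEGORIES[i], 3)
    hi1 <- audit12_risk(FREQUENCY_CATEGORIES[i + 1], 3)
    expect_true(hi1$short_term >= lo1$short_term)
    expect_true(hi1$long_term >= lo1$long_term)
  }
  for (i in 1:4) {
    lo3 <- audit3_risk(FREQUENCY_CATEGORIES[i])
    hi3 <- audit3_risk(FREQUENCY_CATEGORIES[i + 1])
    expect_true(hi3$short_term >= lo3$short_term)
    expect_true(hi3$long_term >= lo3$long_term)
  }
})
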