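test_that("ethanol gram arithmetic matches hand calculation", {
  expect_equal(ethanol_grams(375, 0.048), 375 * 0.048 * 0.789)
  expect_equal(ethanol_grams(375, 0.048), 14.2, tolerance = 0.001)
  expect_equal(ethanol_grams(1000, 0.10, share = 0.5), 39.45)
  expect_equal(ethanol_grams(500, 0.2, fullness = 0), 0)
})

test_that("gram conversion is linear in count and share", {
  set.seed(11)
  for (i in 1:20) {
    vol <- runif(1, 50, 2000)
    abv <- runif(1, 0.01, 0.6)
    s <- runif(1)
    cnt <- runif(1, 0, 5)
    base <- ethanol_grams(vol, abv, count = cnt)
    expect_equal(ethanol_grams(vol, abv, count = 2 * cnt), 2 * base)
    expect_equal(ethanol_grams(vol, abv, share = s, count = cnt), s * base)
    # a shared half-can is the same via count or share
    expect_equal(ethanol_grams(vol, abv, count = 0.5),
                 ethanol_grams(vol, abv, share = 0.5))
  }
})

test_that("invalid beverage inputs are rejected naming the field", {
  expect_error(ethanol_grams(-10, 0.05), "volume_ml")
  expect_error(ethanol_grams(375, 1.5), "abv")
  expect_error(ethanol_grams(375, 0.05, fullness = -0.1), "fullness")
  expect_error(ethanol_grams(375, 0.05, count = -1), "count")
  expect_error(standard_drinks(-1), "grams")
})

test_that("standard drinks are grams over ten", {
  expect_equal(standard_drinks(10), 1.0)
  expect_equal(standard_drinks(0), 0)
  expect_equal(standard_drinks(39.45), 3.945)
  # a 10 g entry is exactly one standard drink
  g <- ethanol_grams(10 / (0.05 * 0.789), 0.05)
  expect_equal(standard_drinks(g), 1.0)
})

test_that("occasion totals cover both dialects", {
  cat <- test_catalog()
  expect_equal(occasion_total_drinks(occasion(3, standard_drinks = 16)), 16)
  two_cans <- data.frame(product_id = "beer_can", container_volume_ml = 375,
                         fullness = 1, count = 2, share = 1)
  expect_equal(occasion_total_drinks(occasion(3, entries = two_cans), cat),
               2 * 375 * 0.048 * 0.789 / 10)
  expect_equal(occasion_total_drinks(occasion(3, entries = two_cans), cat),
               2.84, tolerance = 0.001)
  empty <- two_cans[0, ]
  expect_equal(occasion_total_drinks(occasion(3, entries = empty), cat), 0)
})

test_that("unknown products and malformed occasions fail loudly", {
  cat <- test_catalog()
  bad <- data.frame(product_id = "mystery_brew", container_volume_ml = 375,
                    fullness = 1, count = 1, share = 1)
  expect_error(occasion_total_drinks(occasion(1, entries = bad), cat),
               "mystery_brew")
  expect_error(occasion(-1, standard_drinks = 2), "days_before_survey")
  expect_error(occasion(1), "exactly one")
  expect_error(occasion(1, standard_drinks = 2,
                        entries = bad), "exactly one")
})

test_that("composed beverage lists round-trip to the target drinks", {
  cat <- test_catalog()
  per_can <- standard_drinks(ethanol_grams(375, 0.048))
  one_can <- compose_beverages(per_can, cat)
  expect_equal(nrow(one_can), 1)
  expect_equal(one_can$fullness, 1)
  expect_equal(nrow(compose_beverages(0, cat)), 0)
  set.seed(21)
  for (target in c(0.3, 1, 4.9, 16, 23.7, runif(10, 0, 60))) {
    entries <- compose_beverages(target, cat)
    got <- occasion_total_drinks(occasion(0, entries = entries), cat)
    expect_equal(got, target, tolerance = 1e-9)
  }
  expect_error(compose_beverages(5, test_catalog()[0, ]), "catalog")
})
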