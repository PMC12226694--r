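test_that("Wilson bounds match the closed form at zero events", {
  # at x = 0 the Wilson upper bound is z^2 / (n + z^2)
  z <- qnorm(0.975)
  for (n in c(7, 23, 68, 93)) {
    ci <- wilson_interval(0, n)
    expect_equal(ci$lower, 0)
    expect_equal(ci$upper, z^2 / (n + z^2), tolerance = 1e-12)
  }
  ci <- wilson_interval(7, 11)
  expect_lt(abs(ci$lower - 0.354), 1e-3)
  expect_lt(abs(ci$upper - 0.848), 1e-3)
})

test_that("zero-event and all-event Wilson intervals are mirror images", {
  for (n in c(1, 5, 20, 68)) for (level in c(0.9, 0.95, 0.99)) {
    lo <- wilson_interval(0, n, level)
    hi <- wilson_interval(n, n, level)
    expect_equal(lo$lower, 1 - hi$upper, tolerance = 1e-12)
    expect_equal(lo$upper, 1 - hi$lower, tolerance = 1e-12)
  }
})

test_that("Clopper-Pearson agrees with binom.test and its closed forms", {
  for (case in list(c(1, 2), c(0, 7), c(3, 10), c(6, 9))) {
    ci <- clopper_pearson_interval(case[1], case[2])
    oracle <- binom.test(case[1], case[2])$conf.int
    expect_equal(ci$lower, oracle[1], tolerance = 1e-9)
    expect_equal(ci$upper, oracle[2], tolerance = 1e-9)
  }
  # x = 0: upper bound has closed form 1 - (alpha/2)^(1/n)
  expect_equal(clopper_pearson_interval(0, 7)$upper, 1 - 0.025^(1 / 7),
               tolerance = 1e-12)
  ci <- clopper_pearson_interval(0, 1)
  expect_equal(c(ci$lower, ci$upper), c(0, 0.975), tolerance = 1e-12)
})

test_that("intervals nest with level and shrink with trials", {
  for (make in list(wilson_interval, clopper_pearson_interval)) {
    narrow <- make(3, 10, 0.90)
    wide <- make(3, 10, 0.99)
    expect_lte(wide$lower, narrow$lower)
    expect_gte(wide$upper, narrow$upper)
    widths <- vapply(c(10, 100, 1000, 10000), function(n) {
      ci <- make(round(0.3 * n), n)
      ci$upper - ci$lower
    }, numeric(1))
    expect_true(all(diff(widths) < 0))
    expect_lt(widths[4], 0.02)
  }
})

test_that("interval constructors enforce their preconditions", {
  expect_error(wilson_interval(0, 0), "trials")
  expect_error(clopper_pearson_interval(0, 0), "trials")
  expect_error(wilson_interval(5, 3), "events")
  expect_error(binom_ci(1, 2, level = 1.2), "level")
  ci <- binom_ci(1, 2, method = "clopper_pearson")
  expect_equal(ci$method, "clopper_pearson")
  expect_true(ci$lower <= ci$point && ci$point <= ci$upper)
})

test_that("report rounding is half away from zero, whole percents", {
  expect_equal(format_percent_ci(wilson_interval(7, 11)),
               "64% (95% CI 35-85%)")
  expect_equal(format_percent_ci(clopper_pearson_interval(1, 2)),
               "50% (95% CI 1-99%)")
})
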