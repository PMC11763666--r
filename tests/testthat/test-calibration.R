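# Dilution regression, bar-period measurement, contrast gain.

test_that("the regression recovers exact linear relations", {
  ref <- c(0.5, 1, 2, 5, 10, 20) * 1e6
  fit <- fit_dilution_regression(dilution_series(ref, ref))
  expect_equal(fit$m, 1)
  expect_lt(abs(fit$n), 1e-3)
  expect_equal(fit$r_squared, 1)

  fit2 <- fit_dilution_regression(dilution_series(ref, 2 * ref + 1))
  expect_equal(fit2$m, 2, tolerance = 1e-9)
  expect_equal(fit2$n, 1, tolerance = 1e-6)

  # noiseless synthetic series: coefficients to 1e-9
  dev <- 0.93 * ref + 4.2e4
  fit3 <- fit_dilution_regression(dilution_series(ref, dev))
  expect_equal(fit3$m, 0.93, tolerance = 1e-9)
  expect_equal(fit3$n, 4.2e4, tolerance = 1e-6)
  expect_equal(fit3$n_points, 6)
})

test_that("degenerate regressions are refused", {
  expect_error(fit_dilution_regression(dilution_series(c(1, 2), c(1, 2))),
               "3 points")
  expect_error(fit_dilution_regression(dilution_series(c(1, 1, 1),
                                                       c(1, 2, 3))),
               "all equal")
  expect_error(dilution_series(1:3, 1:2), "equal length")
})

test_that("shifting both axes moves only the intercept", {
  set.seed(6)
  ref <- stats::runif(10, 1e6, 5e7)
  dev <- 1.05 * ref + stats::rnorm(10, 0, 1e5)
  f1 <- fit_dilution_regression(dilution_series(ref, dev))
  k <- 3e6
  f2 <- fit_dilution_regression(dilution_series(ref + k, dev + k))
  expect_equal(f2$m, f1$m, tolerance = 1e-9)
  expect_equal(f2$n, f1$n + k * (1 - f1$m), tolerance = 1e-6)
})

test_that("a pure cosine profile measures its own period", {
  x <- (0:127) * 0.5
  p <- 1 + 0.4 * cos(2 * pi * x / 10)
  m <- measure_bar_period(p, 0.5)
  expect_lt(abs(m$period_um - 10), 0.1)
  expect_equal(m$period_um, 2 * m$half_period_um)
  expect_error(measure_bar_period(rep(1, 128), 0.5), "periodicity")
})

test_that("period estimation is pitch-covariant", {
  x1 <- (0:127) * 0.5
  x2 <- (0:255) * 0.25
  m1 <- measure_bar_period(1 + 0.4 * cos(2 * pi * x1 / 10), 0.5)
  m2 <- measure_bar_period(1 + 0.4 * cos(2 * pi * x2 / 10), 0.25)
  expect_lt(abs(m1$period_um - m2$period_um), 0.05)
})

test_that("profile contrast behaves like a Weber contrast", {
  plateau <- rep(1, 40)
  raw <- c(plateau, 1 - 0.3 * sin(seq(0, pi, length.out = 40)), plateau)
  clean <- c(plateau, 1 - 0.6 * sin(seq(0, pi, length.out = 40)), plateau)
  expect_equal(contrast_gain(raw, raw), 1)
  expect_equal(contrast_gain(clean, raw), 2, tolerance = 1e-9)
  expect_true(profile_contrast(raw) >= 0 && profile_contrast(raw) <= 1)
  expect_error(contrast_gain(clean, rep(1, 120)), "zero contrast")
  expect_error(contrast_gain(clean, raw[-1]), "support")
})
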