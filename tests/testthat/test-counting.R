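# Circular Hough detection, grid-search tuning, concentration conversion.

test_that("a blank image yields no detections", {
  expect_equal(nrow(detect_cells(matrix(1, 100, 100), planted_params())), 0)
})

test_that("well-separated planted circles are counted exactly", {
  centers <- data.frame(x = c(40, 160, 100, 40, 160),
                        y = c(40, 40, 100, 160, 160))
  img <- planted_circles(centers)
  det <- detect_cells(img, planted_params())
  expect_equal(nrow(det), 5)
  for (i in seq_len(5)) {
    d <- sqrt((det$x_px - centers$x[i])^2 + (det$y_px - centers$y[i])^2)
    expect_lt(min(d), 2)
  }
  expect_true(all(det$r_px >= 4 & det$r_px <= 9))
  # sorted by descending score
  expect_true(all(diff(det$score) <= 0))
})

test_that("circles closer than min_dist_px are suppressed to one", {
  centers <- data.frame(x = c(95, 107), y = c(100, 100))
  img <- planted_circles(centers)
  det <- detect_cells(img, planted_params(min_dist_px = 20))
  expect_equal(nrow(det), 1)
})

test_that("detection count is monotone in the accumulator threshold", {
  set.seed(4)
  centers <- data.frame(x = stats::runif(8, 20, 180),
                        y = stats::runif(8, 20, 180))
  img <- planted_circles(centers) +
    matrix(stats::rnorm(200 * 200, 0, 0.03), 200, 200)
  thresholds <- c(0.05, 0.15, 0.3, 0.5, 0.8, 1.2)
  counts <- vapply(thresholds, function(a) {
    p <- planted_params()
    p$accumulator_threshold <- a
    nrow(detect_cells(img, p))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("oversized radius ranges are refused", {
  expect_error(detect_cells(matrix(1, 60, 60),
                            cht_params(r_min_px = 10, r_max_px = 30)),
               "half the smaller")
  expect_error(cht_params(r_min_px = 5, r_max_px = 3), "r_min_px")
})

test_that("grid search returns the zero-error parameters", {
  centers <- data.frame(x = c(50, 150, 100), y = c(50, 60, 150))
  fixtures <- list(list(img = planted_circles(centers), true_count = 3))
  tuned <- tune_cht(fixtures,
                    grid = list(edge_threshold = c(0.02, 0.5)),
                    base = planted_params())
  expect_equal(tuned$mae, 0)
  expect_equal(tuned$params$edge_threshold, 0.02)

  single <- tune_cht(fixtures, grid = list(edge_threshold = 0.5),
                     base = planted_params())
  expect_equal(single$params$edge_threshold, 0.5)

  # tie: both grid points give identical error; the first in order wins
  tie <- tune_cht(fixtures,
                  grid = list(edge_threshold = c(0.02, 0.025)),
                  base = planted_params())
  expect_equal(tie$params$edge_threshold, 0.02)

  expect_error(tune_cht(list(), list(edge_threshold = 1)), "non-empty")
  expect_error(tune_cht(fixtures, list()), "non-empty")
  expect_error(tune_cht(fixtures, list(bogus = 1)), "unknown")
})

test_that("counts convert to concentrations by the imaged volume", {
  expect_equal(to_concentration(0, 1, 500)$concentration_per_ml, 0)
  r <- to_concentration(1000, 1, 500)
  expect_equal(r$volume_ml, 5e-4)
  expect_equal(r$concentration_per_ml, 2e6)
  expect_equal(to_concentration(400, 1, 500)$concentration_per_ml, 8e5)
  # exact linearity in count
  expect_equal(to_concentration(4000, 1, 500)$concentration_per_ml,
               10 * to_concentration(400, 1, 500)$concentration_per_ml)
  expect_error(to_concentration(10, 0, 500), "positive")
  expect_error(to_concentration(10, 1, -5), "positive")
})

test_that("tuned counting tracks truth across the counting range", {
  # reduced-scale stochastic suite: captures across the range, tuned
  # parameters, relative count error within 15% for at least 80% of the
  # non-empty fixtures
  g <- capture_geometry()
  sims <- simulate_dilution_series(c(2e6, 1e7, 5e7), g, canvas_px = 256,
                                   chamber_depth_um = 250,
                                   replicates = 2, seed = 5)
  pspec <- geometry_propagator(g)
  r_px <- 2.5 / g$sample_pitch_um
  params <- cht_params(r_min_px = round(0.7 * r_px),
                       r_max_px = round(1.3 * r_px),
                       min_dist_px = round(1.7 * r_px),
                       edge_threshold = 0.05,
                       accumulator_threshold = 0.3, preblur_sigma = 2)
  rel_err <- vapply(sims$captures, function(cp) {
    if (cp$n_true == 0) return(NA_real_)
    amp <- Mod(remove_twin_image(normalize_hologram(cp$hologram), pspec,
                                 phase_retrieval_config(5))$values)
    abs(nrow(detect_cells(amp, params)) - cp$n_true) / cp$n_true
  }, numeric(1))
  rel_err <- rel_err[!is.na(rel_err)]
  expect_gt(length(rel_err), 3)
  expect_gte(mean(rel_err <= 0.15), 0.8)
})
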