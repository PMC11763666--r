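# Synthetic-data generator: rasterization, USAF line widths, capture
# geometry, noise determinism, dilution series.

test_that("rendered samples are unit-background transmission images", {
  empty <- render_sample(sample_spec(32, 0.5))
  expect_equal(Mod(empty$values), matrix(1, 32, 32))

  one <- render_sample(sample_spec(64, 0.5,
    circles = data.frame(x_um = 16, y_um = 16, r_um = 5, border_t = 0,
                         body_t = 0.15, border_w_um = 1)))
  amp <- Mod(one$values)
  expect_equal(amp[round(16 / 0.5), round(16 / 0.5)], 0.15)
  expect_equal(amp[64, 64], 1)
  expect_true(all(amp >= 0 & amp <= 1))
})

test_that("the two-circle phantom has exactly three plateaus", {
  amp <- Mod(two_circle_field()$values)
  plateau <- c(0, 0.15, 1)
  on_plateau <- Reduce(`|`, lapply(plateau, function(p) abs(amp - p) < 1e-9))
  # every off-plateau pixel is an anti-aliased edge pixel: strictly between
  # neighbouring plateau levels, and a thin minority of the image
  expect_true(all(sapply(plateau, function(p) sum(abs(amp - p) < 1e-9) > 50)))
  expect_lt(mean(!on_plateau), 0.05)
  expect_true(all(amp >= 0 & amp <= 1))
})

test_that("USAF line widths follow the chart formula", {
  expect_equal(round(usaf_half_period(7, 6), 2), 2.19)
  expect_equal(usaf_half_period(0, 1), 500)
  expect_equal(usaf_half_period(1, 1), 250)
  expect_error(usaf_half_period(7, 7), "element")
})

test_that("capture geometry derives magnification and effective distance", {
  g <- capture_geometry(z1_um = 750, z2_um = 9250)
  expect_equal(g$magnification, 40 / 3)
  expect_equal(g$z_eff_um, 750 * 9250 / 10000)
  expect_lt(g$z_eff_um, min(g$z1_um, g$z2_um))
  expect_equal(g$sample_pitch_um, 2.4 / g$magnification)
  expect_error(capture_geometry(z1_um = 0), "positive")
})

test_that("an on-axis noiseless capture is the forward model", {
  g <- capture_geometry()
  f <- render_sample(sample_spec(128, g$sample_pitch_um,
    circles = data.frame(x_um = 10, y_um = 12, r_um = 2.5, border_t = 0,
                         body_t = 0.15, border_w_um = 0.6)))
  h <- simulate_capture(f, g, led = c(0, 0))
  ref <- Mod(forward_propagate(f, geometry_propagator(g))$values)
  expect_lt(max(abs(h$amplitude - ref)), 1e-10)
})

test_that("captures are bit-identical under a fixed seed", {
  g <- capture_geometry()
  f <- render_sample(sample_spec(64, g$sample_pitch_um,
    circles = data.frame(x_um = 5, y_um = 6, r_um = 2, border_t = 0,
                         body_t = 0.15, border_w_um = 0.5)))
  nm <- noise_model(seed = 5, photon_budget = 5000, read_noise_sigma = 10)
  h1 <- simulate_capture(f, g, led = c(1, 0), noise = nm)
  h2 <- simulate_capture(f, g, led = c(1, 0), noise = nm)
  expect_identical(h1$amplitude, h2$amplitude)
  expect_identical(h1$background, h2$background)
  expect_error(noise_model(photon_budget = 100), "seed")
})

test_that("an off-axis LED shifts the hologram by the projective shadow", {
  g <- capture_geometry(z1_um = 750, z2_um = 9250)
  f <- render_sample(sample_spec(256, g$sample_pitch_um,
    circles = data.frame(x_um = c(18, 30), y_um = c(20, 28), r_um = 2.5,
                         border_t = 0, body_t = 0.15, border_w_um = 0.6)))
  h0 <- simulate_capture(f, g, led = c(0, 0))
  h1 <- simulate_capture(f, g, led = c(0, 1))
  # cross-correlate: the peak displacement is the applied shift
  a <- h0$amplitude - mean(h0$amplitude)
  b <- h1$amplitude - mean(h1$amplitude)
  cc <- Re(stats::fft(stats::fft(b) * Conj(stats::fft(a)), inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  shift <- ((pk - 1 + 128) %% 256) - 128  # (dy, dx), wrapped
  expected_dx <- -1 * 4.0 * (9250 / 750) / 2.4  # -20.6 camera px
  expect_equal(shift[["row"]], 0)
  expect_lt(abs(shift[["col"]] - expected_dx), 1)
  expect_equal(attr(h1, "shift_px")[2], expected_dx)
})

test_that("dilution volumes and guards follow the counting range", {
  expect_equal(holocount:::expected_cell_count(2e6, 1, 500), 1000)
  g <- capture_geometry()
  expect_error(simulate_dilution_series(0, g), "range")
  expect_error(simulate_dilution_series(1e5, g), "range")
  expect_error(simulate_dilution_series(5e7, g, canvas_px = 512,
                                        chamber_depth_um = 15000),
               "overcrowded")
})

test_that("dilution series are reproducible and labelled", {
  g <- capture_geometry()
  s1 <- simulate_dilution_series(8e6, g, canvas_px = 64,
                                 chamber_depth_um = 3000,
                                 replicates = 2, seed = 3)
  s2 <- simulate_dilution_series(8e6, g, canvas_px = 64,
                                 chamber_depth_um = 3000,
                                 replicates = 2, seed = 3)
  expect_identical(vapply(s1$captures, `[[`, 0L, "n_true"),
                   vapply(s2$captures, `[[`, 0L, "n_true"))
  expect_identical(s1$captures[[1]]$hologram$amplitude,
                   s2$captures[[1]]$hologram$amplitude)
  expect_false(identical(s1$captures[[1]]$n_true, NULL))
})

test_that("cell counts are Poisson with the analytic expectation", {
  # 200 seeded replicates at one concentration; compare the mean true
  # count with conc * FOV * depth (tiny canvas keeps rendering cheap)
  g <- capture_geometry()
  canvas <- 64
  depth <- 3000
  sims <- simulate_dilution_series(5e7, g, canvas_px = canvas,
                                   chamber_depth_um = depth,
                                   replicates = 200, seed = 17,
                                   noise_photon_budget = NULL,
                                   noise_read_sigma = 0)
  counts <- vapply(sims$captures, `[[`, 0L, "n_true")
  lambda <- holocount:::expected_cell_count(5e7, sims$meta$fov_area_mm2,
                                            depth)
  se <- sqrt(lambda / 200)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
})
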