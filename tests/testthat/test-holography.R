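# Core wave optics: normalization, propagation, reconstruction,
# twin-image removal, focus search.

test_that("normalization divides out the background illumination", {
  B <- matrix(2, 32, 32)
  h <- normalize_hologram(hologram(B, 2.4), B)
  expect_equal(h$normalized, matrix(0, 32, 32))

  h2 <- normalize_hologram(hologram(matrix(3, 32, 32), 2.4), matrix(2, 32, 32))
  expect_equal(h2$normalized, matrix(0.5, 32, 32))

  # normalize(B * (1 + H0'), B) recovers H0' for any H0' > -1
  set.seed(11)
  H0p <- matrix(stats::runif(32 * 32, -0.9, 2), 32, 32)
  B <- matrix(stats::runif(32 * 32, 0.5, 1.5), 32, 32)
  h3 <- normalize_hologram(hologram(B * (1 + H0p), 2.4), B)
  expect_equal(h3$normalized, H0p, tolerance = 1e-12)
})

test_that("background zeros follow the zero policy", {
  B <- matrix(2, 32, 32); B[5, 7] <- 0
  h <- hologram(matrix(3, 32, 32), 2.4)
  expect_error(normalize_hologram(h, B), "zero")
  hz <- normalize_hologram(h, B, zero_policy = "epsilon")
  expect_equal(hz$normalized[5, 7], 3 / 2 - 1)  # min positive value is 2
  expect_error(normalize_hologram(h, matrix(1, 16, 16)), "shape")
})

test_that("forward propagation is a pure-phase transfer", {
  spec <- fixture_spec()
  ones <- complex_field(matrix(1, 64, 64), 0.5)
  out <- forward_propagate(ones, spec)
  expect_equal(out$values, ones$values, tolerance = 1e-12)

  f <- two_circle_field()
  z0 <- forward_propagate(f, fixture_spec(z = 0))
  expect_lt(max(Mod(z0$values - f$values)), 1e-10)

  # Parseval: power conserved through propagation
  out <- forward_propagate(f, spec)
  expect_equal(field_power(out), field_power(f),
               tolerance = 1e-9)
})

test_that("backward propagation inverts forward propagation", {
  f <- two_circle_field()
  set.seed(3)
  for (k in 1:5) {
    spec <- propagator_spec(stats::runif(1, 0.4, 0.7),
                            stats::runif(1, -2000, 2000),
                            0.5)
    rt <- backward_propagate(forward_propagate(f, spec), spec)
    expect_lt(max(Mod(rt$values - f$values)), 1e-10)
    expect_equal(field_power(forward_propagate(f, spec)), field_power(f),
                 tolerance = 1e-9)
  }
  # backward over z == forward over -z
  spec <- fixture_spec(z = 750)
  b <- backward_propagate(f, spec)
  fneg <- forward_propagate(f, fixture_spec(z = -750))
  expect_lt(max(Mod(b$values - fneg$values)), 1e-12)
})

test_that("discarding the phase at the detector loses information", {
  f <- two_circle_field()
  spec <- fixture_spec()
  det <- forward_propagate(f, spec)
  full_rt <- backward_propagate(det, spec)
  amp_only <- backward_propagate(
    complex_field(Mod(det$values), 0.5, plane = "detector"), spec)
  err_full <- rmse(Mod(full_rt$values), Mod(f$values))
  err_amp <- rmse(Mod(amp_only$values), Mod(f$values))
  expect_gt(err_amp, err_full)
  expect_gt(err_amp, 1e-3)  # visible twin-image ripples
})

test_that("single-step reconstruction finds the cells", {
  spec <- fixture_spec()
  h <- hologram_of(two_circle_field(), spec)
  rec <- reconstruct(h, spec)
  amp <- as.matrix(EBImage::gblur(Mod(rec$values), 2))
  # local minima of the smoothed amplitude, deepest first
  shifts <- expand.grid(dy = -1:1, dx = -1:1)
  nbr_min <- Reduce(pmin, lapply(seq_len(nrow(shifts)), function(i) {
    if (shifts$dy[i] == 0 && shifts$dx[i] == 0) return(matrix(Inf, 128, 128))
    roll_image(amp, shifts$dy[i], shifts$dx[i])
  }))
  mins <- which(amp < nbr_min)
  mins <- mins[order(amp[mins])][1:2]  # the two deepest
  my <- ((mins - 1) %% 128) + 1
  mx <- ((mins - 1) %/% 128) + 1
  centers <- data.frame(x = c(20, 40) / 0.5 + 0.5, y = c(24, 36) / 0.5 + 0.5)
  d_to <- function(i) sqrt((mx - centers$x[i])^2 + (my - centers$y[i])^2)
  expect_lt(min(d_to(1)), 4)
  expect_lt(min(d_to(2)), 4)
})

test_that("reconstruction is deterministic", {
  set.seed(99)
  H <- matrix(stats::runif(64 * 64, 0.5, 1.5), 64, 64)
  h <- normalize_hologram(hologram(H, 0.5),
                          background = matrix(1, 64, 64))
  spec <- fixture_spec()
  r1 <- reconstruct(h, spec)
  r2 <- reconstruct(h, spec)
  expect_identical(r1$values, r2$values)
  expect_error(reconstruct(hologram(H, 0.5), spec), "normalized")
})

test_that("twin-image removal reduces reconstruction error", {
  spec <- fixture_spec()
  truth <- Mod(two_circle_field()$values)
  h <- hologram_of(two_circle_field(), spec)
  rec0 <- remove_twin_image(h, spec, phase_retrieval_config(0))
  rec5 <- remove_twin_image(h, spec, phase_retrieval_config(5))
  expect_identical(rec0$values, reconstruct(h, spec)$values)
  expect_lt(rmse(Mod(rec5$values), truth), rmse(Mod(rec0$values), truth))
})

test_that("an empty constraint mask is a fixed point", {
  spec <- fixture_spec()
  h <- hologram_of(two_circle_field(), spec)
  peak <- max(Mod(reconstruct(h, spec)$values))
  cfg <- phase_retrieval_config(5, clip_level = 2 * peak)
  rec5 <- remove_twin_image(h, spec, cfg)
  rec0 <- reconstruct(h, spec)
  expect_lt(max(Mod(rec5$values - rec0$values)), 1e-10)
})

test_that("a degenerate constraint raises an error", {
  # uniform H0 = 5 reconstructs to amplitude 6 everywhere: full mask
  h <- hologram(matrix(6, 32, 32), 0.5, normalized = matrix(5, 32, 32))
  expect_error(remove_twin_image(h, fixture_spec(), phase_retrieval_config(1)),
               "degenerac")
})

test_that("focus sweep recovers the simulation distance", {
  spec <- fixture_spec(z = 1000)
  h <- hologram_of(two_circle_field(), spec)
  sweep <- focus_sweep(h, spec, z_range = seq(700, 1300, by = 50))
  expect_equal(sweep$best_z, 1000)
  expect_equal(focus_sweep(h, spec, z_range = 850)$best_z, 850)
  expect_error(focus_sweep(h, spec, numeric(0)), "non-empty")
  h0 <- hologram(matrix(0, 32, 32), 0.5, normalized = matrix(-1, 32, 32))
  expect_error(focus_sweep(h0, spec, c(900, 1000)), "undefined")
})
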