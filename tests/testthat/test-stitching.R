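# Feature matching, affine fitting, mosaic composition, apodization.

test_that("an image matches itself with zero displacement", {
  tex <- seeded_texture()
  m <- match_features(tex, tex)
  expect_gte(nrow(m), 3)
  expect_equal(stats::median(abs(m$x_a - m$x_b)), 0)
  expect_equal(stats::median(abs(m$y_a - m$y_b)), 0)
})

test_that("matching recovers a planted translation", {
  tex <- seeded_texture()
  texb <- roll_image(tex, -7, 12)  # features move by (dx, dy) = (12, -7)
  m <- match_features(tex, texb)
  expect_gte(nrow(m), 3)
  expect_lt(abs(stats::median(m$x_b - m$x_a) - 12), 0.5)
  expect_lt(abs(stats::median(m$y_b - m$y_a) - (-7)), 0.5)
})

test_that("featureless images cannot be matched", {
  flat <- matrix(1, 64, 64)
  expect_error(match_features(flat, flat), "constant|insufficient")
})

test_that("affine fitting solves exact correspondences exactly", {
  set.seed(8)
  truth <- affine_transform(a = 1.02, b = -0.03, c = 14.5,
                            d = 0.02, e = 0.98, f = -6.25)
  xb <- stats::runif(40, 1, 200); yb <- stats::runif(40, 1, 200)
  p <- apply_affine(truth, xb, yb)
  m <- data.frame(x_a = p$x, y_a = p$y, x_b = xb, y_b = yb)
  fit <- fit_affine(m)
  for (cf in c("a", "b", "c", "d", "e", "f"))
    expect_equal(fit[[cf]], truth[[cf]], tolerance = 1e-9)

  expect_error(fit_affine(m[1:2, ]), "3 correspondences")
  coll <- data.frame(x_a = 1:5, y_a = 1:5, x_b = 1:5, y_b = 2 * (1:5))
  coll$x_b <- 1:5; coll$y_b <- 1:5  # collinear source points
  expect_error(fit_affine(coll), "rank|collinear")
})

test_that("affine fitting is robust to coordinate noise", {
  set.seed(21)
  truth <- affine_transform(a = 1.01, b = 0.02, c = 25, d = -0.02,
                            e = 0.99, f = 11)
  xb <- stats::runif(100, 1, 300); yb <- stats::runif(100, 1, 300)
  p <- apply_affine(truth, xb, yb)
  m <- data.frame(x_a = p$x + stats::rnorm(100, 0, 0.5),
                  y_a = p$y + stats::rnorm(100, 0, 0.5),
                  x_b = xb, y_b = yb)
  fit <- fit_affine(m)
  expect_gt(attr(fit, "residual_rms"), 0.25)
  expect_lt(attr(fit, "residual_rms"), 1.0)
  expect_lt(abs(fit$a - truth$a), 0.02)
  expect_lt(abs(fit$e - truth$e), 0.02)
})

test_that("fitting is scale-consistent", {
  set.seed(5)
  xb <- stats::runif(50, 1, 100); yb <- stats::runif(50, 1, 100)
  truth <- affine_transform(a = 0.97, b = 0.05, c = 8, d = -0.04,
                            e = 1.03, f = -3)
  p <- apply_affine(truth, xb, yb)
  m <- data.frame(x_a = p$x, y_a = p$y, x_b = xb, y_b = yb)
  s <- 2.5
  ms <- data.frame(x_a = s * m$x_a, y_a = s * m$y_a,
                   x_b = s * m$x_b, y_b = s * m$y_b)
  f1 <- fit_affine(m, trim = FALSE)
  f2 <- fit_affine(ms, trim = FALSE)
  expect_equal(f2$a, f1$a, tolerance = 1e-9)
  expect_equal(f2$b, f1$b, tolerance = 1e-9)
  expect_equal(f2$e, f1$e, tolerance = 1e-9)
  expect_equal(f2$c, s * f1$c, tolerance = 1e-9)
  expect_equal(f2$f, s * f1$f, tolerance = 1e-9)
})

test_that("a single image with identity transform is its own mosaic", {
  tex <- seeded_texture(n = 80)
  mos <- compose_mosaic(list(tex), list(affine_transform()))
  expect_equal(dim(mos$image), dim(tex))
  expect_equal(mos$image, tex, tolerance = 1e-12)
  expect_true(all(mos$weight == 1))
})

test_that("overlapping crops reassemble the reference texture", {
  ref <- seeded_texture(n = 200, seed = 31)
  a <- ref[1:120, 1:120]
  b <- ref[1:120, 61:180]  # 50% horizontal overlap, true shift dx = 60
  mos <- compose_mosaic(list(a, b),
                        list(affine_transform(),
                             affine_transform(c = 60)))
  valid <- mos$valid
  sub_ref <- ref[1:120, 1:180]
  expect_gt(stats::cor(mos$image[valid], sub_ref[valid]), 0.95)
  expect_gt(sum(valid), length(a))  # mosaic area exceeds a single image

  # permutation insensitivity under mean blending
  mos2 <- compose_mosaic(list(b, a),
                         list(affine_transform(c = 60), affine_transform()))
  expect_lt(max(abs(mos$image[valid] - mos2$image[mos2$valid])), 1e-12)
})

test_that("disconnected stacks are refused", {
  tex <- seeded_texture(n = 60, seed = 2)
  expect_error(compose_mosaic(list(tex, tex),
                              list(affine_transform(),
                                   affine_transform(c = 500, f = 500))),
               "disconnected")
})

test_that("apodization tapers only the borders", {
  tex <- seeded_texture(n = 100, seed = 9) + 0.1
  ap <- apodize(tex, 0.1)
  expect_equal(ap[50, 50], tex[50, 50])
  expect_equal(ap[30, 45], tex[30, 45])
  expect_equal(ap[1, ], rep(0, 100))
  expect_equal(ap[, 100], rep(0, 100))
  expect_lt(sum(ap^2), sum(tex^2))
  expect_error(apodize(tex, 0.6), "margin_fraction")
  expect_error(apodize(tex, 0), "margin_fraction")
})

test_that("stack alignment recovers the LED-shift ground truth", {
  g <- capture_geometry()
  set.seed(13)
  n_cells <- 14
  ext <- 256 * g$sample_pitch_um
  cx <- stats::runif(n_cells, 4, ext - 4)
  cy <- stats::runif(n_cells, 4, ext - 4)
  f <- render_sample(sample_spec(256, g$sample_pitch_um,
    circles = data.frame(x_um = cx, y_um = cy, r_um = 2.5, border_t = 0,
                         body_t = 0.15, border_w_um = 0.6)))
  leds <- expand.grid(col = -1:1, row = -1:1)[, c("row", "col")]
  stack <- lapply(seq_len(nrow(leds)), function(k) {
    h <- simulate_capture(f, g, led = as.integer(leds[k, ]),
                          noise = noise_model(seed = 100 + k,
                                              photon_budget = 2e4))
    normalize_hologram(h)$normalized
  })
  transforms <- align_stack(stack)
  shift_per_led <- -g$led_pitch_um * g$z2_um / g$z1_um / g$camera_pitch_um
  err <- vapply(seq_len(nrow(leds)), function(k) {
    expected_dx <- (leds$col[k] - leds$col[1]) * shift_per_led
    expected_dy <- (leds$row[k] - leds$row[1]) * shift_per_led
    # transform maps image k into the anchor frame; for pure translation
    # the offset is (c, f) and content shifted by s maps back by -s
    max(abs(transforms[[k]]$c + expected_dx),
        abs(transforms[[k]]$f + expected_dy))
  }, numeric(1))
  expect_gte(mean(err <= 1), 0.9)
})
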