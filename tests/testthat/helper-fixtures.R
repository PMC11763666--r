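# Fixtures are built in code; nothing is stored on disk.

# Two-cell phantom: opaque border ring, semi-transparent body, on a
# 128 x 128 canvas at 0.5 um/px (64 x 64 um extent).
two_circle_spec <- function() {
  sample_spec(128, 0.5,
              circles = data.frame(x_um = c(20, 40), y_um = c(24, 36),
                                   r_um = 5, border_t = 0, body_t = 0.15,
                                   border_w_um = 1))
}

two_circle_field <- function() render_sample(two_circle_spec())

# Hologram of a field under plane-wave illumination (unit background).
hologram_of <- function(field, spec) {
  H <- Mod(forward_propagate(field, spec)$values)
  normalize_hologram(hologram(H, field$pitch_um,
                              background = matrix(1, nrow(H), ncol(H))))
}

fixture_spec <- function(z = 1000) propagator_spec(0.468, z, 0.5)

# Smooth random texture with localizable blobs, for feature matching.
seeded_texture <- function(n = 180, seed = 42, sigma = 2) {
  set.seed(seed)
  as.matrix(EBImage::gblur(matrix(stats::runif(n * n), n, n), sigma))
}

# Integer circular shift: content moves by (dy, dx).
roll_image <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  m[((seq_len(nr) - 1 - dy) %% nr) + 1, ((seq_len(nc) - 1 - dx) %% nc) + 1]
}

# Raster image with planted dark circles on a bright background.
planted_circles <- function(centers, r_px = 6, dim_px = 200, depth = 0.9) {
  img <- matrix(1, dim_px, dim_px)
  xs <- col(img); ys <- row(img)
  for (i in seq_len(nrow(centers)))
    img[(xs - centers$x[i])^2 + (ys - centers$y[i])^2 <= r_px^2] <- 1 - depth
  img
}

planted_params <- function(r_px = 6, min_dist_px = 20)
  cht_params(r_min_px = max(2, r_px - 2), r_max_px = r_px + 3,
             min_dist_px = min_dist_px, edge_threshold = 0.02,
             accumulator_threshold = 0.3, preblur_sigma = 1.5)

rmse <- function(a, b) sqrt(mean((a - b)^2))
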