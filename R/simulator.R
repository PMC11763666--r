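# Synthetic-data generator: transmission samples (circle cells, three-bar
# resolution targets), point-source capture geometry, seeded noise, and
# dilution-series capture sets.  This module is the fixture source for the
# rest of the pipeline.

#' Transmission-sample specification
#'
#' Describes an amplitude-only specimen on a unit-transmission background:
#' a set of circular "cells" (an opaque border ring of a given width and a
#' semi-transparent body, the standard two-level cell phantom) and/or a
#' three-bar resolution pattern.
#'
#' @param canvas_px Grid size in pixels, one number (square) or `c(rows,
#'   cols)`.
#' @param pitch_um Sample-plane sampling pitch, micrometres per pixel.
#' @param circles Data frame with columns `x_um`, `y_um` (centre, measured
#'   from the top-left corner), `r_um`, `border_t`, `body_t`,
#'   `border_w_um`.  Circles must lie fully inside the canvas; overlaps are
#'   allowed (last drawn wins).
#' @param bars Optional list with `half_period_um` (line width), and
#'   optionally `n_bars` (default 3), `orientation` (`"vertical"` bars vary
#'   along x, `"horizontal"` along y), `t` (bar transmission, default 0) and
#'   `length_factor` (bar length in units of the line width, default 5 as on
#'   standard resolution charts).
#' @param background Background transmission in `[0, 1]`, default 1.
#' @return An object of class `sample_spec`.
#' @seealso [render_sample()]
#' @export
sample_spec <- function(canvas_px, pitch_um, circles = NULL, bars = NULL,
                        background = 1) {
  if (length(canvas_px) == 1L) canvas_px <- c(canvas_px, canvas_px)
  canvas_px <- as.integer(canvas_px)
  if (any(canvas_px < 16L)) stop("canvas must be at least 16 x 16 px")
  if (pitch_um <= 0) stop("`pitch_um` must be positive")
  if (background < 0 || background > 1)
    stop("background transmission must be in [0, 1]")
  if (!is.null(circles)) {
    circles <- as.data.frame(circles)
    need <- c("x_um", "y_um", "r_um", "border_t", "body_t", "border_w_um")
    if (!all(need %in% names(circles)))
      stop("`circles` needs columns: ", paste(need, collapse = ", "))
    if (any(circles$r_um <= 0)) stop("circle radii must be positive")
    if (any(circles$border_t < 0 | circles$border_t > 1 |
            circles$body_t < 0 | circles$body_t > 1))
      stop("transmissions must be in [0, 1]")
    ext_y <- canvas_px[1] * pitch_um
    ext_x <- canvas_px[2] * pitch_um
    if (any(circles$x_um - circles$r_um < 0 | circles$x_um + circles$r_um > ext_x |
            circles$y_um - circles$r_um < 0 | circles$y_um + circles$r_um > ext_y))
      stop("circles must lie fully inside the canvas")
  }
  if (!is.null(bars)) {
    defaults <- list(n_bars = 3L, orientation = "vertical", t = 0,
                     length_factor = 5)
    bars <- utils::modifyList(defaults, bars)
    if (is.null(bars$half_period_um) || bars$half_period_um <= 0)
      stop("`bars$half_period_um` must be positive")
    if (bars$t < 0 || bars$t > 1) stop("bar transmission must be in [0, 1]")
    if (!bars$orientation %in% c("vertical", "horizontal"))
      stop("bar orientation must be \"vertical\" or \"horizontal\"")
  }
  structure(list(canvas_px = canvas_px, pitch_um = as.numeric(pitch_um),
                 circles = circles, bars = bars,
                 background = as.numeric(background)),
            class = "sample_spec")
}

# Fine-grid column coordinates (um) for supersampled rasterization.
fine_coords <- function(n, pitch, ss) (seq_len(n * ss) - 0.5) * (pitch / ss)

#' Rasterize a transmission sample
#'
#' Renders the specimen described by a [sample_spec()] onto its pixel grid.
#' Rasterization is done on a grid supersampled `supersample`-fold per axis
#' and block-averaged down, which anti-aliases circle and bar edges; all
#' output amplitudes lie in `[0, 1]`.
#'
#' @param spec A [sample_spec()].
#' @param supersample Supersampling factor per axis (default 4).
#' @return A [complex_field()] at the sample plane (amplitude-only).
#' @examples
#' sp <- sample_spec(64, 0.5,
#'   circles = data.frame(x_um = 16, y_um = 16, r_um = 5,
#'                        border_t = 0, body_t = 0.15, border_w_um = 1))
#' f <- render_sample(sp)
#' range(Mod(f$values))
#' @export
render_sample <- function(spec, supersample = 4L) {
  stopifnot(inherits(spec, "sample_spec"))
  ss <- as.integer(supersample)
  if (ss < 1L) stop("`supersample` must be >= 1")
  nr <- spec$canvas_px[1]; nc <- spec$canvas_px[2]
  pf <- spec$pitch_um / ss
  t <- matrix(spec$background, nr * ss, nc * ss)
  ys <- fine_coords(nr, spec$pitch_um, ss)
  xs <- fine_coords(nc, spec$pitch_um, ss)
  if (!is.null(spec$circles)) {
    for (i in seq_len(nrow(spec$circles))) {
      ci <- spec$circles[i, ]
      rows <- which(abs(ys - ci$y_um) <= ci$r_um + pf)
      cols <- which(abs(xs - ci$x_um) <= ci$r_um + pf)
      d2 <- outer((ys[rows] - ci$y_um)^2, (xs[cols] - ci$x_um)^2, "+")
      sub <- t[rows, cols]
      sub[d2 <= ci$r_um^2] <- ci$border_t
      rin <- max(ci$r_um - ci$border_w_um, 0)
      sub[d2 <= rin^2] <- ci$body_t
      t[rows, cols] <- sub
    }
  }
  if (!is.null(spec$bars)) {
    b <- spec$bars
    hp <- b$half_period_um
    span <- (2 * b$n_bars - 1) * hp
    len <- b$length_factor * hp
    cx <- nc * spec$pitch_um / 2
    cy <- nr * spec$pitch_um / 2
    along <- if (b$orientation == "vertical") xs else ys
    across <- if (b$orientation == "vertical") ys else xs
    a0 <- (if (b$orientation == "vertical") cx else cy) - span / 2
    in_bar <- rep(FALSE, length(along))
    for (k in seq_len(b$n_bars) - 1L)
      in_bar <- in_bar | (along >= a0 + 2 * k * hp & along < a0 + (2 * k + 1) * hp)
    c0 <- if (b$orientation == "vertical") cy else cx
    in_len <- across >= c0 - len / 2 & across <= c0 + len / 2
    if (b$orientation == "vertical") t[in_len, in_bar] <- b$t
    else t[in_bar, in_len] <- b$t
  }
  if (ss > 1L) {
    m <- matrix(0, nr, nc)
    for (i in seq_len(ss)) for (j in seq_len(ss))
      m <- m + t[seq(i, nr * ss, by = ss), seq(j, nc * ss, by = ss)]
    t <- m / ss^2
  }
  complex_field(t, spec$pitch_um, plane = "sample")
}

#' Line width (half-period) of a USAF-1951 element
#'
#' The standard chart resolves `2^(group + (element - 1) / 6)` line pairs per
#' millimetre, so the line width is `500 / 2^(group + (element - 1) / 6)`
#' micrometres.  Group 7 element 6 gives 2.19 um.
#'
#' @param group Integer group number.
#' @param element Element number in 1..6.
#' @return Line width in micrometres.
#' @examples
#' usaf_half_period(7, 6)  # 2.19
#' @export
usaf_half_period <- function(group, element) {
  if (!is.numeric(element) || length(element) != 1L ||
      element != round(element) || element < 1 || element > 6)
    stop("`element` must be an integer in 1..6")
  if (!is.numeric(group) || length(group) != 1L || group != round(group))
    stop("`group` must be an integer")
  500 / 2^(group + (element - 1) / 6)
}

#' Point-source capture geometry
#'
#' Geometry of the lensless microscope: an LED point source at distance
#' `z1` below the sample and a camera at distance `z2` above it.  The
#' spherical illumination magnifies the in-line hologram by
#' `M = (z1 + z2) / z1`, and propagation is equivalent to a plane wave over
#' the effective distance `z_eff = z1 * z2 / (z1 + z2)` on a grid
#' demagnified to `camera_pitch_um / M` (the sample-frame pitch).
#'
#' @param z1_um Source-sample distance (micrometres, > 0).
#' @param z2_um Sample-camera distance (micrometres, > 0).
#' @param camera_pitch_um Camera pixel pitch (default 2.4 um/px).
#' @param led_pitch_um Microdisplay LED pitch (default 4.0 um/px).
#' @param wavelength_um Peak LED wavelength (default 0.468 um, blue).
#' @return An object of class `capture_geometry` with derived fields
#'   `magnification`, `z_eff_um` and `sample_pitch_um`.
#' @examples
#' g <- capture_geometry(z1_um = 750, z2_um = 9250)
#' g$magnification   # 13.33
#' g$z_eff_um        # 693.75
#' @export
capture_geometry <- function(z1_um = 750, z2_um = 9250,
                             camera_pitch_um = 2.4, led_pitch_um = 4.0,
                             wavelength_um = 0.468) {
  if (z1_um <= 0 || z2_um <= 0) stop("`z1_um` and `z2_um` must be positive")
  if (camera_pitch_um <= 0 || led_pitch_um <= 0 || wavelength_um <= 0)
    stop("pitches and wavelength must be positive")
  M <- (z1_um + z2_um) / z1_um
  structure(list(z1_um = z1_um, z2_um = z2_um,
                 camera_pitch_um = camera_pitch_um,
                 led_pitch_um = led_pitch_um,
                 wavelength_um = wavelength_um,
                 magnification = M,
                 z_eff_um = z1_um * z2_um / (z1_um + z2_um),
                 sample_pitch_um = camera_pitch_um / M),
            class = "capture_geometry")
}

#' Reconstruction propagator for a capture geometry
#'
#' Convenience constructor for the [propagator_spec()] that reconstructs
#' holograms captured under `geom`: wavelength and effective distance from
#' the geometry, pitch equal to the sample-frame (demagnified camera) pitch.
#'
#' @param geom A [capture_geometry()].
#' @export
geometry_propagator <- function(geom) {
  stopifnot(inherits(geom, "capture_geometry"))
  propagator_spec(geom$wavelength_um, geom$z_eff_um, geom$sample_pitch_um)
}

#' Detector noise and illumination model
#'
#' Emulates the main degradations of a real capture: LED intensity
#' variation across the field (a smooth multiplicative gain), photon shot
#' noise (Poisson with `photon_budget` expected counts at unit amplitude
#' squared), and additive Gaussian read noise in counts.
#'
#' @param seed RNG seed; required whenever any stochastic component is
#'   active.  Capture functions derive independent per-image substreams
#'   from it, so identical arguments give bit-identical images.
#' @param photon_budget Expected photon counts at unit intensity, or `NULL`
#'   to disable shot noise.
#' @param read_noise_sigma Additive Gaussian sigma in counts (>= 0; only
#'   meaningful with a photon budget).
#' @param illumination_profile Optional positive gain matrix (recycled to
#'   the canvas) multiplying the incident amplitude, or `NULL` for uniform
#'   illumination.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(seed = NULL, photon_budget = NULL,
                        read_noise_sigma = 0, illumination_profile = NULL) {
  if (!is.null(photon_budget) && photon_budget <= 0)
    stop("`photon_budget` must be positive when present")
  if (read_noise_sigma < 0) stop("`read_noise_sigma` must be >= 0")
  stochastic <- !is.null(photon_budget) || read_noise_sigma > 0
  if (stochastic && is.null(seed))
    stop("a `seed` is required when noise is enabled")
  structure(list(seed = if (is.null(seed)) NULL else as.integer(seed),
                 photon_budget = photon_budget,
                 read_noise_sigma = read_noise_sigma,
                 illumination_profile = illumination_profile),
            class = "noise_model")
}

# Evaluate a function with a private, restored RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  force(expr)
}

# Apply the noise model to an amplitude image; `substream` decorrelates the
# sample capture from its background capture.
apply_noise <- function(A, noise, substream = 0L) {
  if (!is.null(noise$illumination_profile)) {
    gain <- noise$illumination_profile
    if (!is.matrix(gain) || !all(dim(gain) == dim(A)))
      stop("illumination profile shape does not match the canvas")
    if (any(gain <= 0)) stop("illumination profile must be strictly positive")
    A <- A * gain
  }
  if (!is.null(noise$photon_budget) || noise$read_noise_sigma > 0) {
    budget <- if (is.null(noise$photon_budget)) 1e12 else noise$photon_budget
    A <- with_seed(noise$seed + 7919L * substream, {
      counts <- stats::rpois(length(A), budget * as.numeric(A)^2)
      if (noise$read_noise_sigma > 0)
        counts <- counts + stats::rnorm(length(A), 0, noise$read_noise_sigma)
      matrix(sqrt(pmax(counts, 0) / budget), nrow(A), ncol(A))
    })
  }
  A
}

# Subpixel circular shift of a real image by (dy, dx) pixels via a Fourier
# phase ramp.
fourier_shift <- function(img, dy, dx) {
  fr <- fft_freq(nrow(img))
  fc <- fft_freq(ncol(img))
  ramp <- exp(-2i * pi * outer(fr * dy, fc * dx, "+"))
  Re(ifft2(fft2(img) * ramp))
}

#' Simulate one hologram capture
#'
#' Forward-propagates an amplitude sample over the effective distance of a
#' point-source geometry (in the demagnified sample frame), shifts the
#' detector pattern according to the addressed LED, applies the noise model
#' and records the matching background image (same illumination and noise
#' statistics, no sample).
#'
#' An LED displaced by `delta = led_index * led_pitch_um` from the optical
#' axis casts the projective shadow of the sample shifted by
#' `-delta * z2 / z1` at the detector (in detector micrometres).  The shift
#' is applied as a subpixel Fourier translation on the propagator's
#' periodic canvas (content leaving one edge re-enters at the opposite
#' one, consistent with the FFT-periodic forward model); the applied shift
#' is reported in sample-frame pixels.
#'
#' @param sample A [complex_field()] at the sample plane.  If its pitch does
#'   not equal the geometry's sample-frame pitch it is resampled bilinearly.
#' @param geom A [capture_geometry()].
#' @param led Integer `c(row, col)` LED index relative to the optical axis;
#'   `c(0, 0)` is on-axis.
#' @param noise A [noise_model()].
#' @return A [hologram()] (detector amplitude + background, pitch =
#'   `camera_pitch_um`), with attributes `shift_px` (applied sample-frame
#'   pixel shift, `c(dy, dx)`) and `geometry`.
#' @export
simulate_capture <- function(sample, geom, led = c(0L, 0L),
                             noise = noise_model()) {
  stopifnot(inherits(sample, "holo_field"), inherits(geom, "capture_geometry"),
            inherits(noise, "noise_model"))
  if (length(led) != 2L) stop("`led` must be c(row, col)")
  sp <- geom$sample_pitch_um
  if (abs(sample$pitch_um - sp) > 1e-9 * sp)
    sample <- resample_field(sample, sp)
  spec <- propagator_spec(geom$wavelength_um, geom$z_eff_um, sp)
  A <- Mod(forward_propagate(sample, spec)$values)
  shift_det_um <- -as.numeric(led) * geom$led_pitch_um * geom$z2_um / geom$z1_um
  shift_px <- shift_det_um / geom$camera_pitch_um  # = sample-frame px
  if (any(abs(shift_px) >= dim(A))) {
    warning("LED shift moves the pattern fully off-canvas; wrapping clipped")
    shift_px <- shift_px %% dim(A)
  }
  if (any(shift_px != 0)) A <- pmax(fourier_shift(A, shift_px[1], shift_px[2]), 0)
  B <- matrix(1, nrow(A), ncol(A))
  A_obs <- apply_noise(A, noise, substream = 0L)
  B_obs <- apply_noise(B, noise, substream = 1L)
  out <- hologram(A_obs, geom$camera_pitch_um, background = B_obs)
  attr(out, "shift_px") <- shift_px
  attr(out, "geometry") <- geom
  out
}

# Bilinear resampling of a complex field onto a new pitch over the same
# physical extent.
resample_field <- function(field, new_pitch) {
  v <- field$values
  nr <- max(16L, round(nrow(v) * field$pitch_um / new_pitch))
  nc <- max(16L, round(ncol(v) * field$pitch_um / new_pitch))
  ys <- ((seq_len(nr) - 0.5) * new_pitch) / field$pitch_um + 0.5
  xs <- ((seq_len(nc) - 0.5) * new_pitch) / field$pitch_um + 0.5
  g <- expand.grid(y = ys, x = xs)
  re <- bilinear_sample(Re(v), g$x, g$y)
  im <- bilinear_sample(Im(v), g$x, g$y)
  vals <- matrix(complex(real = re$value, imaginary = im$value), nr, nc)
  complex_field(vals, new_pitch, plane = field$plane)
}

# Expected number of cells in the imaged volume.
expected_cell_count <- function(concentration_per_ml, fov_area_mm2,
                                chamber_depth_um) {
  concentration_per_ml * fov_area_mm2 * chamber_depth_um * 1e-6
}

# Uniform cell placement with soft overlap rejection: draws centres one by
# one, redrawing (up to `max_retries` times) any centre closer than
# `min_sep_factor` times the radius sum to an accepted centre, then
# accepting the overlap (settled monolayers do touch occasionally).
place_cells <- function(n, extent_um, radius_um, min_sep_factor = 1.2,
                        max_retries = 100L) {
  if (length(extent_um) == 1L) extent_um <- c(extent_um, extent_um)
  lo <- radius_um
  hi_x <- extent_um[2] - radius_um
  hi_y <- extent_um[1] - radius_um
  if (hi_x <= lo || hi_y <= lo) stop("canvas too small for the cell radius")
  min_sep <- min_sep_factor * 2 * radius_um
  xs <- numeric(0); ys <- numeric(0)
  for (i in seq_len(n)) {
    for (try in seq_len(max_retries + 1L)) {
      x <- stats::runif(1, lo, hi_x)
      y <- stats::runif(1, lo, hi_y)
      if (length(xs) == 0L ||
          min(sqrt((xs - x)^2 + (ys - y)^2)) >= min_sep ||
          try > max_retries) break
    }
    xs <- c(xs, x); ys <- c(ys, y)
  }
  data.frame(x_um = xs, y_um = ys)
}

#' Simulate a labelled dilution series of cell captures
#'
#' For each concentration level and replicate, draws a Poisson number of
#' cells for the imaged volume (field-of-view area times chamber depth),
#' places centres uniformly with soft overlap rejection, renders the cells
#' (opaque border ring, semi-transparent body) and simulates an on-axis
#' capture with background.  Ground-truth counts and centres are returned
#' with every capture, which makes the series the reference arm for counting
#' and calibration experiments.
#'
#' @param concentrations_per_ml Concentration levels in cells/mL; each must
#'   lie in the counting range `[5e5, 5e7]` of the device.
#' @param geom A [capture_geometry()].
#' @param canvas_px Detector canvas size in pixels (square).
#' @param chamber_depth_um Depth of the imaged liquid layer (micrometres).
#' @param replicates Replicates per level.
#' @param seed Base RNG seed; each capture uses a derived substream.
#' @param cell_radius_um Cell radius (default 2.5 um, a typical budding-yeast
#'   half-diameter).
#' @param body_t,border_t,border_w_um Cell transmission model: body and
#'   border transmission and border ring width.
#' @param noise_photon_budget,noise_read_sigma Capture noise (see
#'   [noise_model()]); set the budget to `NULL` for noiseless captures.
#' @return An object of class `dilution_captures`: a list with `captures`
#'   (one record per image: `concentration_per_ml`, `replicate`, `n_true`,
#'   `centers`, `hologram`) and `meta` (geometry, FOV area, depth, seed).
#' @section Overcrowding guard:
#' Levels whose expected count exceeds 5000 cells per field of view are
#' refused; that regime is outside the countable monolayer range.
#' @export
simulate_dilution_series <- function(concentrations_per_ml, geom,
                                     canvas_px = 512L,
                                     chamber_depth_um = 100,
                                     replicates = 3L, seed = 1L,
                                     cell_radius_um = 2.5,
                                     body_t = 0.15, border_t = 0,
                                     border_w_um = 0.6,
                                     noise_photon_budget = 10000,
                                     noise_read_sigma = 20) {
  stopifnot(inherits(geom, "capture_geometry"))
  if (any(concentrations_per_ml < 5e5 | concentrations_per_ml > 5e7))
    stop("concentrations must lie in the counting range 0.5-50 million cells/mL")
  if (chamber_depth_um <= 0) stop("`chamber_depth_um` must be positive")
  sp <- geom$sample_pitch_um
  extent_um <- canvas_px * sp
  fov_area_mm2 <- (extent_um * 1e-3)^2
  captures <- list()
  k <- 0L
  for (ci in seq_along(concentrations_per_ml)) {
    conc <- concentrations_per_ml[ci]
    lambda <- expected_cell_count(conc, fov_area_mm2, chamber_depth_um)
    if (lambda > 5000)
      stop("expected count ", round(lambda), " per FOV exceeds 5000; ",
           "overcrowded regime refused")
    for (rep_i in seq_len(replicates)) {
      k <- k + 1L
      item_seed <- as.integer(seed) + 1000L * ci + rep_i
      placed <- with_seed(item_seed, {
        n <- stats::rpois(1, lambda)
        list(n = n,
             centers = place_cells(n, extent_um, cell_radius_um))
      })
      circles <- if (placed$n > 0)
        data.frame(x_um = placed$centers$x_um, y_um = placed$centers$y_um,
                   r_um = cell_radius_um, border_t = border_t,
                   body_t = body_t, border_w_um = border_w_um)
      else NULL
      spec <- sample_spec(canvas_px, sp, circles = circles)
      field <- render_sample(spec)
      nm <- if (is.null(noise_photon_budget) && noise_read_sigma == 0)
        noise_model()
      else noise_model(seed = item_seed + 500000L,
                       photon_budget = noise_photon_budget,
                       read_noise_sigma = noise_read_sigma)
      holo <- simulate_capture(field, geom, led = c(0L, 0L), noise = nm)
      captures[[k]] <- list(concentration_per_ml = conc, replicate = rep_i,
                            n_true = placed$n, centers = placed$centers,
                            hologram = holo)
    }
  }
  structure(list(captures = captures,
                 meta = list(geometry = geom, canvas_px = canvas_px,
                             fov_area_mm2 = fov_area_mm2,
                             chamber_depth_um = chamber_depth_um,
                             seed = as.integer(seed),
                             cell_radius_um = cell_radius_um)),
            class = "dilution_captures")
}
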