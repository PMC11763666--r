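# End-to-end desk experiments: resolution measurement on a simulated
# three-bar target and dilution-series counting calibration.  These wrap
# the simulator, holography, counting and calibration modules into the two
# quantitative studies the pipeline is built for.

#' Simulated resolution experiment on a three-bar target
#'
#' Renders a three-bar pattern with the line width of the requested
#' USAF-1951 element at the sample-frame pitch of the capture geometry,
#' forward-propagates it over the effective distance, reconstructs with
#' `iterations` twin-image-removal steps (and, for comparison, with the
#' plain single-step reconstruction), extracts the mean profile
#' perpendicular to the bars over the central bar rows, and measures the
#' dominant half-period and the contrast of both profiles.
#'
#' @param geom A [capture_geometry()].
#' @param group,element USAF group/element selecting the line width.
#' @param canvas_px Simulation canvas (square, sample-frame pixels).
#' @param iterations Twin-image removal iterations (default 5).
#' @param segment_halfspan Half-width of the analysed profile segment, as a
#'   multiple of the bar-pattern span (default 0.9).
#' @return A list with `half_period_um` (cleaned reconstruction),
#'   `measurement` (the [measure_bar_period()] result), `contrast_gain`
#'   (cleaned over single-step), `profile_clean`, `profile_raw`,
#'   `profile_pitch_um` and `line_width_um` (the ground truth).
#' @export
usaf_resolution_experiment <- function(geom = capture_geometry(),
                                       group = 7, element = 6,
                                       canvas_px = 384L, iterations = 5L,
                                       segment_halfspan = 0.9) {
  hp <- usaf_half_period(group, element)
  sp <- geom$sample_pitch_um
  spec <- sample_spec(canvas_px, sp, bars = list(half_period_um = hp))
  target <- render_sample(spec)
  holo <- simulate_capture(target, geom)
  holo <- normalize_hologram(holo)
  pspec <- geometry_propagator(geom)
  rec_raw <- reconstruct(holo, pspec)
  rec_clean <- remove_twin_image(holo, pspec,
                                 phase_retrieval_config(iterations))
  # mean profile across the central bar rows, perpendicular to the bars
  extent <- canvas_px * sp
  ys <- (seq_len(canvas_px) - 0.5) * sp
  rows <- which(abs(ys - extent / 2) < 2 * hp)
  span_px <- 5 * hp / sp
  cols <- round(canvas_px / 2 - segment_halfspan * span_px):
    round(canvas_px / 2 + segment_halfspan * span_px)
  prof_raw <- colMeans(Mod(rec_raw$values)[rows, cols])
  prof_clean <- colMeans(Mod(rec_clean$values)[rows, cols])
  meas <- measure_bar_period(prof_clean, sp)
  list(half_period_um = meas$half_period_um,
       measurement = meas,
       contrast_gain = contrast_gain(prof_clean, prof_raw),
       profile_clean = prof_clean, profile_raw = prof_raw,
       profile_pitch_um = sp, line_width_um = hp)
}

#' End-to-end dilution-series counting experiment
#'
#' Simulates a labelled dilution series, tunes the circular-Hough detector
#' on dedicated control captures (their ground-truth counts stand in for
#' manually counted control samples), runs the full per-image pipeline
#' (normalize, twin-image-removed reconstruction, CHT count, concentration
#' conversion) and regresses the recovered concentration on the
#' ground-truth concentration.
#'
#' @param geom A [capture_geometry()].
#' @param concentrations_per_ml Dilution levels (default: 6 levels
#'   geometrically spanning 0.5-50 million cells/mL).
#' @param replicates Replicates per level.
#' @param seed Base seed for the whole experiment.
#' @param canvas_px,chamber_depth_um Imaged geometry, passed to
#'   [simulate_dilution_series()].
#' @param iterations Twin-image removal iterations.
#' @param tune_grid Named list of CHT parameter axes to search; `NULL`
#'   searches `edge_threshold` and `accumulator_threshold` around defaults
#'   scaled for the cell radius.
#' @param n_controls Control captures per control level (one sparse level at
#'   8 and one dense at 50 million cells/mL, so the grid search sees both
#'   missed-detection and false-positive regimes).
#' @return A list with `fit` (a [calibration_fit()]), `results` (per-image
#'   data frame: true and recovered counts and concentrations), `params`
#'   (tuned [cht_params()]) and `meta`.
#' @export
run_dilution_experiment <- function(geom = capture_geometry(),
                                    concentrations_per_ml =
                                      0.5e6 * 100^(0:5 / 5),
                                    replicates = 3L, seed = 1L,
                                    canvas_px = 512L,
                                    chamber_depth_um = 100,
                                    iterations = 5L,
                                    tune_grid = NULL,
                                    n_controls = 2L) {
  pspec <- geometry_propagator(geom)
  cfg <- phase_retrieval_config(iterations)
  r_px <- 2.5 / geom$sample_pitch_um  # default cell radius in px
  base <- cht_params(r_min_px = max(2, round(0.7 * r_px)),
                     r_max_px = round(1.3 * r_px),
                     min_dist_px = round(1.7 * r_px),
                     edge_threshold = 0.05,
                     accumulator_threshold = 0.3,
                     preblur_sigma = 2)
  # default values first: grid ties resolve to the first point in
  # iteration order, so the default stays preferred unless the controls
  # discriminate
  if (is.null(tune_grid))
    tune_grid <- list(edge_threshold = c(0.05, 0.03, 0.08),
                      accumulator_threshold = c(0.3, 0.2, 0.45))
  recon_amp <- function(h) {
    hn <- normalize_hologram(h)
    Mod(remove_twin_image(hn, pspec, cfg)$values)
  }
  # control captures spanning the counting range (a sparse and a dense
  # field), disjoint seed substream; dense controls are what lets the grid
  # search penalize false-positive votes between crowded cells
  ctrl <- simulate_dilution_series(c(8e6, 5e7), geom, canvas_px = canvas_px,
                                   chamber_depth_um = chamber_depth_um,
                                   replicates = n_controls,
                                   seed = as.integer(seed) + 900000L)
  fixtures <- lapply(ctrl$captures, function(cp)
    list(img = recon_amp(cp$hologram), true_count = cp$n_true))
  tuned <- tune_cht(fixtures, tune_grid, base = base)
  sims <- simulate_dilution_series(concentrations_per_ml, geom,
                                   canvas_px = canvas_px,
                                   chamber_depth_um = chamber_depth_um,
                                   replicates = replicates, seed = seed)
  fov <- sims$meta$fov_area_mm2
  depth <- sims$meta$chamber_depth_um
  rows <- lapply(sims$captures, function(cp) {
    det <- detect_cells(recon_amp(cp$hologram), tuned$params)
    data.frame(concentration_per_ml = cp$concentration_per_ml,
               replicate = cp$replicate,
               n_true = cp$n_true,
               n_detected = nrow(det),
               true_conc = to_concentration(cp$n_true, fov,
                                            depth)$concentration_per_ml,
               device_conc = to_concentration(nrow(det), fov,
                                              depth)$concentration_per_ml)
  })
  results <- do.call(rbind, rows)
  series <- dilution_series(reference = results$true_conc,
                            device = results$device_conc,
                            dilution = results$concentration_per_ml,
                            replicate = results$replicate)
  list(fit = fit_dilution_regression(series),
       results = results,
       params = tuned$params,
       meta = list(geometry = geom, fov_area_mm2 = fov,
                   chamber_depth_um = depth, seed = as.integer(seed),
                   tuning_mae = tuned$mae))
}
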