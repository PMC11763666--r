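# End-to-end pipeline entry points used by the command-line wrapper:
# simulate a multi-LED capture stack to disk, and process a stack through
# normalize -> stitch -> reconstruct -> twin-image removal -> count.

#' Simulate a multi-LED capture stack to disk
#'
#' Places cells at the configured concentration, captures one hologram per
#' LED of the configured grid (row-major raster order) plus a background,
#' and writes the numbered 16-bit TIFF stack with its JSON sidecar
#' (geometry, LED indices, seed, amplitude scales, ground truth).
#'
#' @param config A pipeline config (see [default_config()]).
#' @param out_dir Output directory.
#' @return Invisibly, the sidecar path.
#' @export
cli_simulate <- function(config = default_config(), out_dir) {
  config <- validate_config(config)
  geom <- config_geometry(config)
  sm <- config$simulate
  sp <- geom$sample_pitch_um
  extent_um <- sm$canvas_px * sp
  fov_area_mm2 <- (extent_um * 1e-3)^2
  depth <- config$counting$chamber_depth_um
  lambda <- expected_cell_count(sm$concentration_per_ml, fov_area_mm2, depth)
  placed <- with_seed(config$seed, {
    n <- stats::rpois(1, lambda)
    list(n = n, centers = place_cells(n, extent_um, 2.5))
  })
  circles <- if (placed$n > 0)
    data.frame(x_um = placed$centers$x_um, y_um = placed$centers$y_um,
               r_um = 2.5, border_t = 0, body_t = 0.15, border_w_um = 0.6)
  else NULL
  field <- render_sample(sample_spec(sm$canvas_px, sp, circles = circles))
  off <- function(n) (seq_len(n) - 1L - n %/% 2L) * sm$led_stride
  leds <- as.matrix(expand.grid(col = off(sm$led_cols),
                                row = off(sm$led_rows)))[, c("row", "col"),
                                                         drop = FALSE]
  holograms <- lapply(seq_len(nrow(leds)), function(k) {
    nm <- if (is.null(sm$photon_budget) && sm$read_noise_sigma == 0)
      noise_model()
    else noise_model(seed = config$seed + 13L * k,
                     photon_budget = sm$photon_budget,
                     read_noise_sigma = sm$read_noise_sigma)
    simulate_capture(field, geom, led = leds[k, ], noise = nm)
  })
  truth <- list(n_cells = placed$n,
                centers_um = as.list(placed$centers),
                concentration_per_ml = sm$concentration_per_ml,
                chamber_depth_um = depth)
  invisible(write_capture_stack(holograms, leds, geom, out_dir,
                                seed = config$seed, truth = truth))
}

# "Without a background" normalization (captures lacking a background
# image): divide by the mean level instead of B.
normalize_no_background <- function(h) {
  m <- mean(h$amplitude)
  if (m <= 0) stop("cannot normalize an all-zero hologram")
  hologram(h$amplitude, h$pitch_um, normalized = h$amplitude / m - 1)
}

#' Run the full processing pipeline on a capture stack
#'
#' Normalizes every capture (against the recorded background, or against
#' its mean level with `stitching$use_background = FALSE`), chain-aligns
#' and mosaics the stack when it has more than one image (a single image
#' skips stitching), apodizes the mosaic borders, reconstructs with
#' iterative twin-image removal, counts cells with the configured circular
#' Hough transform, and writes all artifacts: mosaic and reconstruction
#' amplitude (32-bit TIFF), per-image transforms (CSV), detections (CSV),
#' counts with concentration (CSV) and a machine-readable run log (JSON:
#' config digest, package versions, per-stage timings, seed).
#'
#' @param stack_dir Directory holding a capture stack
#'   (see [write_capture_stack()]).
#' @param config A pipeline config.
#' @param out_dir Output directory.
#' @return Invisibly, a list with `count`, `concentration_per_ml`,
#'   `detections`, `transforms` and the output paths.
#' @export
cli_pipeline <- function(stack_dir, config = default_config(), out_dir) {
  config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
  }
  stack <- read_capture_stack(stack_dir)
  geom <- stack$geometry
  tick("read")
  use_bg <- isTRUE(config$stitching$use_background)
  has_bg <- !is.null(stack$holograms[[1L]]$background)
  if (use_bg && !has_bg)
    stop("stack has no background image; set stitching.use_background ",
         "to FALSE to normalize without one")
  planes <- lapply(stack$holograms, function(h) {
    if (use_bg) normalize_hologram(h)$normalized
    else normalize_no_background(h)$normalized
  })
  tick("normalize")
  n_img <- length(planes)
  if (n_img > 1L) {
    transforms <- align_stack(planes,
                              ratio_threshold = config$stitching$ratio_threshold,
                              trim = isTRUE(config$stitching$outlier_trim))
    mos <- compose_mosaic(planes, transforms)
    h0 <- mos$image
    h0[!mos$valid] <- 0
    valid <- mos$valid
  } else {
    transforms <- list(affine_transform())
    h0 <- planes[[1L]]
    valid <- matrix(TRUE, nrow(h0), ncol(h0))
  }
  h0 <- apodize(h0, config$stitching$apodize_margin)
  tick("stitch")
  holo <- hologram(abs(1 + h0), geom$camera_pitch_um, normalized = h0)
  pspec <- geometry_propagator(geom)
  cfg_r <- phase_retrieval_config(config$retrieval$iterations,
                                  config$retrieval$clip_level)
  rec <- remove_twin_image(holo, pspec, cfg_r)
  amp <- Mod(rec$values)
  tick("reconstruct")
  det <- detect_cells(amp, config_cht(config))
  fov_area_mm2 <- sum(valid) * (geom$sample_pitch_um * 1e-3)^2
  conc <- to_concentration(nrow(det), fov_area_mm2,
                           config$counting$chamber_depth_um)
  tick("count")
  # artifacts
  paths <- list(
    mosaic = file.path(out_dir, "mosaic.tif"),
    reconstruction = file.path(out_dir, "reconstruction_amplitude.tif"),
    transforms = file.path(out_dir, "transforms.csv"),
    detections = file.path(out_dir, "detections.csv"),
    counts = file.path(out_dir, "counts.csv"),
    run_log = file.path(out_dir, "run_log.json"),
    config = file.path(out_dir, "config_used.yaml"))
  write_hologram_image(h0, paths$mosaic, bits = 32L)
  write_hologram_image(amp, paths$reconstruction, bits = 32L)
  tr <- do.call(rbind, lapply(seq_along(transforms), function(k)
    data.frame(image_id = sprintf("capture_%03d", k - 1L),
               a = transforms[[k]]$a, b = transforms[[k]]$b,
               c = transforms[[k]]$c, d = transforms[[k]]$d,
               e = transforms[[k]]$e, f = transforms[[k]]$f)))
  utils::write.csv(tr, paths$transforms, row.names = FALSE)
  write_detections_csv(det, paths$detections, image_id = "mosaic")
  write_counts_csv(data.frame(image_id = "mosaic", count = nrow(det),
                              concentration_per_ml = conc$concentration_per_ml),
                   paths$counts)
  write_config(config, paths$config)
  log <- list(config_md5 = unname(tools::md5sum(paths$config)),
              seed = config$seed,
              r_version = as.character(getRversion()),
              package_version =
                as.character(utils::packageVersion("holocount")),
              n_images = n_img,
              count = nrow(det),
              concentration_per_ml = conc$concentration_per_ml,
              fov_area_mm2 = fov_area_mm2,
              timings_s = timings)
  jsonlite::write_json(log, paths$run_log, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(count = nrow(det),
                 concentration_per_ml = conc$concentration_per_ml,
                 detections = det, transforms = transforms, paths = paths))
}
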