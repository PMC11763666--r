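# Pipeline configuration: YAML-backed, unit-suffixed keys, validated and
# normalized so that parse(serialize(config)) round-trips exactly.

#' Default pipeline configuration
#'
#' All physical defaults are the device values: wavelength 0.468 um (blue
#' microdisplay LED), camera pitch 2.4 um/px, LED pitch 4.0 um/px, source-
#' sample distance 750 um (the middle of the 500-1000 um working range),
#' source-camera distance 10 mm (so z2 = 9250 um), and N = 5 twin-image
#' removal iterations.  Key names carry explicit unit suffixes (`_um`,
#' `_mm2`) to keep units honest.
#'
#' @return A nested named list of class `pipeline_config`.
#' @export
default_config <- function() {
  cfg <- list(
    geometry = list(wavelength_um = 0.468, z1_um = 750, z2_um = 9250,
                    camera_pitch_um = 2.4, led_pitch_um = 4.0),
    retrieval = list(iterations = 5L, clip_level = 1.0),
    stitching = list(ratio_threshold = 0.75, outlier_trim = TRUE,
                     apodize_margin = 0.1, use_background = TRUE),
    cht = list(r_min_px = 10, r_max_px = 18, min_dist_px = 20,
               edge_threshold = 0.05, accumulator_threshold = 0.3,
               preblur_sigma = 2,
               grid = list(edge_threshold = c(0.03, 0.05, 0.08),
                           accumulator_threshold = c(0.2, 0.3, 0.45))),
    counting = list(chamber_depth_um = 100),
    simulate = list(canvas_px = 256L, led_rows = 8L, led_cols = 8L,
                    led_stride = 1L, concentration_per_ml = 8e6,
                    photon_budget = 10000, read_noise_sigma = 20),
    seed = 1L)
  class(cfg) <- c("pipeline_config", class(cfg))
  cfg
}

# Coerce every leaf to a canonical type so YAML round-trips are identical().
normalize_config <- function(cfg) {
  ints <- c("iterations", "canvas_px", "led_rows", "led_cols", "led_stride",
            "seed")
  walk <- function(x, name = "") {
    if (is.list(x)) {
      out <- lapply(seq_along(x), function(i) walk(x[[i]], names(x)[i]))
      names(out) <- names(x)
      return(out)
    }
    if (is.logical(x)) return(x)
    if (name %in% ints) return(as.integer(x))
    if (is.numeric(x)) return(as.numeric(x))
    x
  }
  out <- walk(unclass(cfg))
  class(out) <- c("pipeline_config", class(out))
  out
}

#' Validate a pipeline configuration
#'
#' Checks the physical geometry (positive distances and pitches), retrieval
#' and counting settings; returns the normalized config or raises a
#' validation error.
#'
#' @param cfg A config list (from [default_config()] or [read_config()]).
#' @return The validated, normalized config.
#' @export
validate_config <- function(cfg) {
  g <- cfg$geometry
  if (is.null(g) || any(vapply(g[c("wavelength_um", "z1_um", "z2_um",
                                   "camera_pitch_um", "led_pitch_um")],
                               function(v) is.null(v) || !is.numeric(v) || v <= 0,
                               logical(1))))
    stop("config validation: geometry distances and pitches must be positive")
  if (is.null(cfg$retrieval) || cfg$retrieval$iterations < 0)
    stop("config validation: retrieval.iterations must be >= 0")
  if (!is.null(cfg$counting$chamber_depth_um) &&
      cfg$counting$chamber_depth_um <= 0)
    stop("config validation: counting.chamber_depth_um must be positive")
  normalize_config(cfg)
}

#' Read / write pipeline configuration (YAML)
#'
#' @param path YAML file path.
#' @return `read_config()` returns a validated `pipeline_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @param cfg A config list.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(normalize_config(cfg)), path, precision = 15L)
  invisible(path)
}

# Geometry object from a config.
config_geometry <- function(cfg) {
  g <- cfg$geometry
  capture_geometry(z1_um = g$z1_um, z2_um = g$z2_um,
                   camera_pitch_um = g$camera_pitch_um,
                   led_pitch_um = g$led_pitch_um,
                   wavelength_um = g$wavelength_um)
}

# CHT params from a config.
config_cht <- function(cfg) {
  p <- cfg$cht
  cht_params(r_min_px = p$r_min_px, r_max_px = p$r_max_px,
             min_dist_px = p$min_dist_px, edge_threshold = p$edge_threshold,
             accumulator_threshold = p$accumulator_threshold,
             preblur_sigma = p$preblur_sigma)
}
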