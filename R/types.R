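#' Complex optical field on a regular grid
#'
#' A 2D complex-valued optical field with a physical sampling pitch.  Matrices
#' are row-major in the image sense: rows run along y (top to bottom), columns
#' along x (left to right).  Fields at the sample plane hold the transmission
#' function `t(x, y)` of the specimen (amplitude-only when the specimen is a
#' pure absorber); fields at the detector plane hold propagated wavefronts or
#' reconstructions.
#'
#' @param values Complex (or real, promoted to complex) matrix, at least
#'   16 x 16.
#' @param pitch_um Physical sampling pitch in micrometres per pixel (> 0).
#' @param plane Either `"sample"` or `"detector"`.
#' @return An object of class `holo_field` with elements `values`, `pitch_um`
#'   and `plane`.
#' @examples
#' f <- complex_field(matrix(1, 32, 32), pitch_um = 0.5)
#' field_power(f)
#' @export
complex_field <- function(values, pitch_um, plane = c("sample", "detector")) {
  plane <- match.arg(plane)
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (nrow(values) < 16L || ncol(values) < 16L)
    stop("field grid must be at least 16 x 16")
  if (!is.complex(values)) {
    if (!is.numeric(values)) stop("`values` must be numeric or complex")
    values <- values + 0i
  }
  if (any(!is.finite(Re(values))) || any(!is.finite(Im(values))))
    stop("field contains non-finite values")
  if (!is.numeric(pitch_um) || length(pitch_um) != 1L || pitch_um <= 0)
    stop("`pitch_um` must be a single positive number")
  structure(list(values = values, pitch_um = as.numeric(pitch_um),
                 plane = plane),
            class = "holo_field")
}

#' Total optical power of a field
#'
#' Sum of squared moduli over the grid.  Free-space propagation with a
#' pure-phase transfer function conserves this quantity (Parseval).
#'
#' @param field A [complex_field()].
#' @return A single non-negative number.
#' @export
field_power <- function(field) {
  stopifnot(inherits(field, "holo_field"))
  sum(Mod(field$values)^2)
}

#' @export
print.holo_field <- function(x, ...) {
  cat(sprintf("<holo_field> %d x %d px, pitch %.4g um, plane '%s', power %.4g\n",
              nrow(x$values), ncol(x$values), x$pitch_um, x$plane,
              field_power(x)))
  invisible(x)
}

#' Detector hologram
#'
#' The real, non-negative amplitude image `H(X, Y)` recorded by the camera,
#' optionally together with the background illumination image `B(X, Y)`
#' (captured with the same LED but no sample) and the normalized contrast
#' hologram `H0(X, Y) = H / B - 1`.
#'
#' @param amplitude Non-negative real matrix `H(X, Y)`.
#' @param pitch_um Physical pixel pitch at the detector, micrometres per
#'   pixel.
#' @param background Optional background image `B(X, Y)`, same shape as
#'   `amplitude`.
#' @param normalized Optional normalized hologram `H0(X, Y)`; usually filled
#'   in by [normalize_hologram()].
#' @return An object of class `hologram`.
#' @seealso [normalize_hologram()], [reconstruct()]
#' @export
hologram <- function(amplitude, pitch_um, background = NULL,
                     normalized = NULL) {
  if (!is.matrix(amplitude) || !is.numeric(amplitude))
    stop("`amplitude` must be a numeric matrix")
  if (any(!is.finite(amplitude))) stop("`amplitude` contains non-finite values")
  if (any(amplitude < 0)) stop("hologram amplitude must be non-negative")
  if (!is.numeric(pitch_um) || length(pitch_um) != 1L || pitch_um <= 0)
    stop("`pitch_um` must be a single positive number")
  if (!is.null(background)) {
    if (!is.matrix(background) || !all(dim(background) == dim(amplitude)))
      stop("`background` must be a matrix with the same shape as `amplitude`")
  }
  if (!is.null(normalized)) {
    if (!is.matrix(normalized) || !all(dim(normalized) == dim(amplitude)))
      stop("`normalized` must be a matrix with the same shape as `amplitude`")
  }
  structure(list(amplitude = amplitude, background = background,
                 normalized = normalized, pitch_um = as.numeric(pitch_um)),
            class = "hologram")
}

#' @export
print.hologram <- function(x, ...) {
  cat(sprintf("<hologram> %d x %d px, pitch %.4g um, background: %s, normalized: %s\n",
              nrow(x$amplitude), ncol(x$amplitude), x$pitch_um,
              if (is.null(x$background)) "no" else "yes",
              if (is.null(x$normalized)) "no" else "yes"))
  invisible(x)
}

#' Paraxial propagator specification
#'
#' Defines the paraxial (Fresnel) transfer function
#' `S(u, v) = exp(-i * pi * lambda * z * (u^2 + v^2))` used for forward
#' propagation, and its conjugate `S*` for backward propagation.  `u`, `v`
#' are spatial frequencies in cycles per micrometre on the standard FFT grid.
#'
#' A point-source (spherical-wave) geometry with source-sample distance `z1`
#' and sample-detector distance `z2` is handled by the effective-distance
#' convention: propagate over `z_eff = z1 * z2 / (z1 + z2)` on a coordinate
#' grid demagnified by `M = (z1 + z2) / z1` (see [capture_geometry()]).
#'
#' @param wavelength_um Illumination wavelength in micrometres (> 0).
#' @param distance_um Signed propagation distance `z` in micrometres.
#' @param pitch_um Sampling pitch (micrometres per pixel) of the plane the
#'   FFT is taken on.
#' @return An object of class `propagator_spec`, with a `paraxial_ok` flag
#'   (TRUE when `max(lambda * f) < 0.5` over the frequency grid, i.e.
#'   `pitch_um > wavelength_um`).  Beyond that bound the quadratic-phase
#'   kernel is still applied but is no longer an accurate small-angle model;
#'   [paraxial_ok()] exposes the flag for callers that want to warn.
#' @examples
#' propagator_spec(0.468, 1000, 0.5)
#' @export
propagator_spec <- function(wavelength_um, distance_um, pitch_um) {
  if (!is.numeric(wavelength_um) || wavelength_um <= 0)
    stop("`wavelength_um` must be positive")
  if (!is.numeric(pitch_um) || pitch_um <= 0)
    stop("`pitch_um` must be positive")
  if (!is.numeric(distance_um) || !is.finite(distance_um))
    stop("`distance_um` must be a finite number")
  structure(list(wavelength_um = as.numeric(wavelength_um),
                 distance_um = as.numeric(distance_um),
                 pitch_um = as.numeric(pitch_um),
                 paraxial_ok = wavelength_um / (2 * pitch_um) < 0.5),
            class = "propagator_spec")
}

#' @rdname propagator_spec
#' @param spec A `propagator_spec`.
#' @export
paraxial_ok <- function(spec) {
  stopifnot(inherits(spec, "propagator_spec"))
  isTRUE(spec$paraxial_ok)
}

#' @export
print.propagator_spec <- function(x, ...) {
  cat(sprintf("<propagator_spec> lambda %.4g um, z %.4g um, pitch %.4g um, paraxial: %s\n",
              x$wavelength_um, x$distance_um, x$pitch_um,
              if (x$paraxial_ok) "ok" else "marginal"))
  invisible(x)
}

#' Phase-retrieval (twin-image removal) configuration
#'
#' Controls the iterative constraint loop of [remove_twin_image()]: number of
#' iterations `N`, the physical amplitude ceiling used to build the
#' sample-plane constraint mask (amplitudes above `clip_level` are clipped to
#' `clip_level` and their phase zeroed), and whether per-iteration diagnostics
#' are recorded.
#'
#' @param iterations Non-negative integer `N`; `N = 0` reduces the algorithm
#'   to the single-step reconstruction.
#' @param clip_level Amplitude ceiling (> 0); 1 is the physical bound for a
#'   transmission sample under unit illumination.
#' @param record_history Record the masked pixel fraction per iteration.
#' @return An object of class `phase_retrieval_config`.
#' @export
phase_retrieval_config <- function(iterations = 5L, clip_level = 1,
                                   record_history = FALSE) {
  if (!is.numeric(iterations) || length(iterations) != 1L ||
      iterations < 0 || iterations != round(iterations))
    stop("`iterations` must be a non-negative integer")
  if (!is.numeric(clip_level) || clip_level <= 0)
    stop("`clip_level` must be positive")
  structure(list(iterations = as.integer(iterations),
                 clip_level = as.numeric(clip_level),
                 record_history = isTRUE(record_history)),
            class = "phase_retrieval_config")
}
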