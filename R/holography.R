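# Core wave optics: normalization, paraxial propagation, reconstruction,
# iterative twin-image removal, focus search.

# FFT sample frequencies, cycles per unit of `d` (DC at index 1, wrapped).
fft_freq <- function(n, d = 1) {
  c(seq.int(0L, floor((n - 1) / 2)), seq.int(-ceiling((n - 1) / 2), -1L)) /
    (n * d)
}

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Quadratic-phase transfer function exp(-i pi lambda z (u^2 + v^2)) on the
# wrapped FFT frequency grid of an nr x nc image sampled at `pitch`.
transfer_function <- function(nr, nc, pitch, wavelength, z) {
  fu <- fft_freq(nr, pitch)
  fv <- fft_freq(nc, pitch)
  exp(-1i * pi * wavelength * z * outer(fu^2, fv^2, "+"))
}

check_pitch <- function(field, spec) {
  if (abs(field$pitch_um - spec$pitch_um) >
      1e-9 * max(field$pitch_um, spec$pitch_um))
    stop("field pitch (", field$pitch_um, " um) does not match propagator pitch (",
         spec$pitch_um, " um)")
}

#' Propagate a complex field forward (sample to detector)
#'
#' Applies the paraxial transfer function
#' `S(u, v) = exp(-i*pi*lambda*z*(u^2 + v^2))` in the frequency domain:
#' `ifft( fft(field) * S )`.  `S` is pure phase, so total power is conserved
#' exactly (up to FFT round-off).
#'
#' @param field A [complex_field()].
#' @param spec A [propagator_spec()]; its pitch must match the field's.
#' @return A [complex_field()] at the detector plane.
#' @seealso [backward_propagate()], [reconstruct()]
#' @export
forward_propagate <- function(field, spec) {
  stopifnot(inherits(field, "holo_field"), inherits(spec, "propagator_spec"))
  check_pitch(field, spec)
  v <- field$values
  S <- transfer_function(nrow(v), ncol(v), spec$pitch_um,
                         spec$wavelength_um, spec$distance_um)
  complex_field(ifft2(fft2(v) * S), field$pitch_um, plane = "detector")
}

#' Propagate a complex field backward (detector to sample)
#'
#' Applies the conjugate transfer function `S*(u, v) =
#' exp(+i*pi*lambda*z*(u^2 + v^2))`; the exact inverse of
#' [forward_propagate()] for the same spec when the full complex field is
#' supplied.  Equivalently, backward propagation over `z` is forward
#' propagation over `-z`.
#'
#' @inheritParams forward_propagate
#' @return A [complex_field()] at the sample plane.
#' @export
backward_propagate <- function(field, spec) {
  stopifnot(inherits(field, "holo_field"), inherits(spec, "propagator_spec"))
  check_pitch(field, spec)
  v <- field$values
  S <- transfer_function(nrow(v), ncol(v), spec$pitch_um,
                         spec$wavelength_um, spec$distance_um)
  complex_field(ifft2(fft2(v) * Conj(S)), field$pitch_um, plane = "sample")
}

#' Normalize a hologram against its background illumination
#'
#' Computes the contrast hologram `H0(X, Y) = H(X, Y) / B(X, Y) - 1`, making
#' the recording independent of the incident LED intensity profile.
#'
#' @param raw A [hologram()]; its `amplitude` is `H`.
#' @param background Background image `B` (same shape, positive where used);
#'   defaults to the background stored in `raw`.
#' @param zero_policy What to do with zeros in `B`: `"error"` refuses,
#'   `"epsilon"` replaces them with the smallest strictly positive background
#'   value before dividing.
#' @return The hologram with its `normalized` plane populated and
#'   `background` stored.
#' @examples
#' h <- hologram(matrix(3, 32, 32), pitch_um = 2.4)
#' normalize_hologram(h, matrix(2, 32, 32))$normalized[1, 1]  # 0.5
#' @export
normalize_hologram <- function(raw, background = raw$background,
                               zero_policy = c("error", "epsilon")) {
  stopifnot(inherits(raw, "hologram"))
  zero_policy <- match.arg(zero_policy)
  if (is.null(background)) stop("no background image available")
  if (!is.matrix(background) || !all(dim(background) == dim(raw$amplitude)))
    stop("background shape does not match hologram shape")
  if (any(!is.finite(background)) || any(background < 0))
    stop("background must be finite and non-negative")
  zeros <- background == 0
  if (any(zeros)) {
    if (zero_policy == "error")
      stop("background contains zero pixels; division undefined ",
           "(use zero_policy = \"epsilon\" to substitute)")
    pos <- background[background > 0]
    if (length(pos) == 0L) stop("background is identically zero")
    background[zeros] <- min(pos)
  }
  hologram(raw$amplitude, raw$pitch_um, background = background,
           normalized = raw$amplitude / background - 1)
}

# Amplitude constraint image used by reconstruct()/remove_twin_image():
# the normalized contrast hologram re-centred on the unit illumination
# carrier, A = |1 + H0| (or |H0| when carrier = FALSE).
measured_amplitude <- function(h, use_raw = FALSE, carrier = TRUE) {
  if (use_raw) return(h$amplitude)
  if (is.null(h$normalized))
    stop("hologram has no normalized plane; run normalize_hologram() first ",
         "or set use_raw = TRUE")
  if (carrier) abs(1 + h$normalized) else abs(h$normalized)
}

#' Single-step holographic reconstruction
#'
#' Treats the measured real image as a zero-phase complex field at the
#' detector and back-propagates it to the sample plane.  By default the
#' normalized hologram is used, re-centred on the unit illumination carrier
#' (`A = |1 + H0|`), so that the reconstruction background sits at amplitude
#' 1; set `carrier = FALSE` to back-propagate `|H0|` directly.  The result
#' contains the object superposed with its out-of-focus twin image.
#'
#' @param h A [hologram()] with a normalized plane (unless `use_raw`).
#' @param spec A [propagator_spec()]; its `pitch_um` defines the sampling of
#'   the reconstruction frame (for point-source captures this is the
#'   demagnified detector pitch, see [capture_geometry()]).
#' @param use_raw Back-propagate the raw amplitude `H` instead of the
#'   normalized plane.
#' @param carrier Re-add the unit carrier to the contrast hologram (default).
#' @return A [complex_field()] at the sample plane.
#' @export
reconstruct <- function(h, spec, use_raw = FALSE, carrier = TRUE) {
  stopifnot(inherits(h, "hologram"), inherits(spec, "propagator_spec"))
  A <- measured_amplitude(h, use_raw, carrier)
  backward_propagate(complex_field(A, spec$pitch_um, plane = "detector"),
                     spec)
}

#' Iterative twin-image removal by constrained phase retrieval
#'
#' Starting from the measured amplitude with zero phase, repeats `N` times:
#' back-propagate to the sample plane; split into amplitude and phase; build
#' the mask `m(x, y)` of pixels whose amplitude exceeds `clip_level`; clip
#' those amplitudes to `clip_level` and zero their phase (a transmission
#' sample cannot amplify the illumination); forward-propagate the constrained
#' field to the detector; keep the new phase and restore the measured
#' amplitude.  The returned reconstruction is the back-propagation of the
#' final detector field; `N = 0` is exactly [reconstruct()].
#'
#' @inheritParams reconstruct
#' @param cfg A [phase_retrieval_config()].
#' @return A [complex_field()] at the sample plane.  When
#'   `cfg$record_history` is set, an attribute `history` holds the masked
#'   pixel fraction per iteration.
#' @section Divergence guard:
#' If the constraint mask ever covers more than 90% of the pixels the
#' constraint is degenerate (the measured image is not a contrast hologram on
#' a unit carrier) and an error is raised.
#' @export
remove_twin_image <- function(h, spec, cfg = phase_retrieval_config(),
                              use_raw = FALSE, carrier = TRUE) {
  stopifnot(inherits(h, "hologram"), inherits(spec, "propagator_spec"),
            inherits(cfg, "phase_retrieval_config"))
  A <- measured_amplitude(h, use_raw, carrier)
  det_field <- complex_field(A, spec$pitch_um, plane = "detector")
  masked_frac <- numeric(0)
  if (cfg$iterations > 0L) {
    for (k in seq_len(cfg$iterations)) {
      samp <- backward_propagate(det_field, spec)
      amp <- Mod(samp$values)
      ph <- Arg(samp$values)
      m <- amp > cfg$clip_level
      frac <- mean(m)
      if (frac > 0.9)
        stop("constraint degeneracy: ", round(100 * frac),
             "% of pixels exceed clip_level; check normalization")
      masked_frac <- c(masked_frac, frac)
      amp[m] <- cfg$clip_level
      ph[m] <- 0
      fwd <- forward_propagate(
        complex_field(amp * exp(1i * ph), spec$pitch_um, plane = "sample"),
        spec)
      det_field <- complex_field(A * exp(1i * Arg(fwd$values)),
                                 spec$pitch_um, plane = "detector")
    }
  }
  out <- backward_propagate(det_field, spec)
  if (cfg$record_history) attr(out, "history") <- masked_frac
  out
}

#' Tamura coefficient of an amplitude image
#'
#' `sqrt(sd(a) / mean(a))`, a standard sharpness/contrast statistic for
#' holographic autofocus.  Undefined for images with non-positive mean or
#' zero variance.
#'
#' @param a Numeric matrix or vector of amplitudes.
#' @return A single non-negative number.
#' @export
tamura_coefficient <- function(a) {
  a <- as.numeric(a)
  m <- mean(a)
  s <- stats::sd(a)
  if (!is.finite(m) || m <= 0 || s == 0)
    stop("Tamura coefficient undefined on a constant or non-positive image")
  sqrt(s / m)
}

#' Focus search over reconstruction distances
#'
#' Reconstructs the hologram at each candidate distance and scores the
#' amplitude sharpness with the Tamura coefficient.  For absorbing samples
#' the coefficient peaks at the in-focus plane (edges are sharpest and the
#' amplitude histogram most bimodal there), so the best distance is the
#' argmax.
#'
#' @param h A [hologram()] with a normalized plane (unless `use_raw`).
#' @param spec_template A [propagator_spec()] providing wavelength and pitch;
#'   its distance is replaced by each candidate.
#' @param z_range Numeric vector of candidate distances (micrometres).
#' @inheritParams reconstruct
#' @return A list with `best_z` and `scores`, a data frame of `z_um` and
#'   `sharpness`.
#' @export
focus_sweep <- function(h, spec_template, z_range, use_raw = FALSE,
                        carrier = TRUE) {
  stopifnot(inherits(h, "hologram"), inherits(spec_template, "propagator_spec"))
  if (length(z_range) == 0L) stop("`z_range` must be non-empty")
  sharp <- vapply(z_range, function(z) {
    spec <- propagator_spec(spec_template$wavelength_um, z,
                            spec_template$pitch_um)
    tamura_coefficient(Mod(reconstruct(h, spec, use_raw, carrier)$values))
  }, numeric(1))
  list(best_z = z_range[which.max(sharp)],
       scores = data.frame(z_um = z_range, sharpness = sharp))
}
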