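---
title: "holocount: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{holocount: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its science: the optical model
and its assumptions, the tunable parameters and why their defaults are
what they are, what the synthetic-data generator does and does not
emulate, the numerical conventions, and the places where a genuinely open
design choice had to be made.

## 1. The optical model

### Geometry

A lensless in-line microscope holds the sample between a point-like LED
source (distance `z1` below the sample, 500–1000 µm in the emulated
device) and a bare CMOS sensor (distance `z2` above it, here 9250 µm so
that source-to-camera is 10 mm).  The spherical illumination projects a
magnified in-line hologram onto the sensor.  The standard equivalence for
this geometry replaces the spherical wave by a plane wave propagated over
the *effective distance*

    z_eff = z1 * z2 / (z1 + z2)

on a coordinate grid demagnified by `M = (z1 + z2)/z1`: a detector pixel
of pitch 2.4 µm samples the specimen plane at `2.4/M` µm (0.18 µm at the
default `z1 = 750` µm).  `capture_geometry()` derives these quantities
once and every module works in this single demagnified frame; nothing
else in the package needs to know the illumination was spherical.

### Propagation

Free-space propagation is the paraxial (Fresnel) transfer function
applied in the FFT domain,

    S(u, v) = exp(-i * pi * lambda * z * (u^2 + v^2)),

with `u, v` the standard wrapped FFT frequencies in cycles/µm (DC at
index 1).  `S` is pure phase, so propagation conserves total power to
round-off; backward propagation applies the conjugate `S*` and inverts
forward propagation exactly when the full complex field is available.
These two facts — Parseval conservation to 1e-9 and round-trip identity
to 1e-10 — are asserted as invariants in the test suite, because every
downstream algorithm silently relies on them.

Two numerical points deserve honesty:

* **Paraxial validity.**  The small-angle form is accurate while
  `lambda * f` stays well below 1 over the frequency grid.  At the 0.18 µm
  sample-frame pitch, the highest representable frequencies exceed that
  bound.  `propagator_spec()` computes a `paraxial_ok` flag
  (`max(lambda * f) < 0.5`) rather than warning on every call; the flag is
  the caller's to act on.  Because simulation and reconstruction use the
  *same* kernel, the pipeline is self-consistent even where the kernel is
  no longer an accurate physical model of steep-angle light.
* **Periodic canvas.**  A single-FFT transfer-function propagator lives
  on a torus: object frequencies whose diffraction would leave the canvas
  wrap around instead.  The simulator embraces this rather than hiding
  it — an off-axis LED shifts the detector pattern by a subpixel Fourier
  translation on the same periodic canvas (content leaving one edge
  re-enters at the other).  An earlier design padded the canvas with a
  unit-transmission apron so that shifted-in content would be "new"
  specimen area, but at this Fresnel regime the propagated pattern is
  grid-size sensitive (the object's high frequencies carry a heavily
  wrapped chirp phase), and padded and unpadded captures diverge; the
  periodic convention is the one that is exactly consistent with the
  forward model.

### Normalization

Real captures vary with LED intensity and stray light.  The contrast
hologram `H0 = H/B - 1` (background `B` captured with the same LED, no
sample) removes the illumination.  `normalize_hologram()` refuses zero
background pixels by default; the `"epsilon"` policy substitutes the
smallest positive background value, for sensors with dead pixels.  When
no background exists at all, the pipeline can divide by the mean level
instead (`stitching$use_background = FALSE`), which preserves fringe
contrast but not illumination flatness.

### Twin-image removal

The camera records only the amplitude, so single-step back-propagation
superposes the object with its defocused conjugate (the twin image).  The
iterative constraint loop implemented in `remove_twin_image()` is:

1. back-propagate the detector field to the sample plane;
2. split amplitude/phase; mask pixels with amplitude above `clip_level`
   (default 1 — a transmission sample cannot amplify light);
3. clip masked amplitudes to `clip_level` and zero the masked phase;
4. forward-propagate; keep the new phase, restore the measured amplitude;
5. repeat `N` times (default 5) and back-propagate once more for the
   result.

Conventions that had to be fixed: the loop restarts at back-propagation
(re-normalization happens once, outside the loop); "zero the phase" means
phase 0, not pi; and the measured amplitude restored in step 4 is
`A = |1 + H0|` — the contrast hologram re-centred on the unit
illumination carrier — so that the clip at 1 is physically meaningful.
`A = |H0|` is available via `carrier = FALSE` but makes the unit-clip
constraint meaningless for weakly scattering samples.  `N = 0` reduces
exactly to `reconstruct()`, and a hologram whose reconstruction never
crosses `clip_level` is a fixed point (the constraint never fires and
propagation is invertible); both are asserted in tests.  If the mask ever
covers more than 90% of pixels the constraint is degenerate — almost
always a normalization mistake — and the loop stops with an error rather
than iterating towards garbage.

On the two-cell phantom the loop cuts the amplitude RMSE against ground
truth by more than half (0.097 to 0.038 at `N = 5` on the 128 px
fixture); the test suite asserts the improvement, not the specific
values.

### Focus search

`focus_sweep()` scores reconstructions with the Tamura coefficient
`sqrt(sd/mean)` of the amplitude.  For absorbing samples the coefficient
*peaks* at the true plane — edges are sharpest and the histogram most
bimodal there — which we verified numerically on simulated captures
before fixing argmax as the convention.  (For phase objects the
literature often minimizes instead; this package targets absorbing
cells.)

## 2. The synthetic-data generator

The simulator is first-class, tested code: it defines the study
conditions for every quantitative claim the package makes about itself.

* **Specimens** are amplitude-only transmission masks on a unit
  background: circles with an opaque border ring and a semi-transparent
  body (border `t = 0`, body `t = 0.15`, ring width 0.6 µm by default),
  and three-bar resolution patterns with the USAF-1951 line width
  `500 / 2^(group + (element-1)/6)` µm.  Cells default to radius 2.5 µm —
  a typical budding-yeast half-diameter; this is a package default, not a
  measured value.  Rasterization is 4x supersampled and block-averaged,
  so edges are anti-aliased and all amplitudes stay in [0, 1].
* **Capture** forward-propagates at `z_eff` in the demagnified frame.  An
  LED at grid offset `delta` shifts the pattern by `-delta * z2/z1`
  detector micrometres (projective shadow geometry), applied as a
  subpixel Fourier translation.
* **Noise** is multiplicative illumination gain, Poisson shot noise with
  a photon budget (default 10000 counts at unit intensity for dilution
  captures, i.e. ~1% amplitude noise) and additive Gaussian read noise
  (default 20 counts).  All noise is seeded; identical arguments give
  bit-identical images, and per-capture substreams decorrelate sample
  and background exposures.
* **Dilution series** draw a Poisson number of cells for the imaged
  volume (FOV area x chamber depth; 1 mm² x 1 µm = 1e-6 mL), place
  centres uniformly with soft overlap rejection (minimum separation 1.2x
  the radius sum, up to 100 redraws, then accept the overlap — settled
  monolayers do touch), and refuse expected counts above 5000 per field
  as uncountably crowded.  Concentrations are restricted to the device's
  counting range, 0.5–50 million cells/mL.

What the generator does **not** emulate: the LED's finite emitter size
and 25 nm spectral width (partial coherence), sensor MTF, sample
thickness, and settling dynamics.  Passing tests therefore demonstrate
the correctness and internal consistency of the algorithms under an
idealized coherent forward model — not the device's full physical error
budget.  Two concrete consequences: simulated captures reconstruct
*better* than real ones (see the contrast-gain note in section 4), and
the dilution-series calibration measures counting fidelity, not optical
robustness.

## 3. Stitching

Multi-LED stacks are aligned pairwise in raster order (image *k* matched
to *k−1*), each pair fitted with two independent ordinary-least-squares
models ("bi-linear": `x'` on `(x, y, 1)` and `y'` on `(x, y, 1)`), and
the chain composed into the first image's frame.  The feature detector is
a compact difference-of-Gaussians scale space (base sigma 1.6, sqrt(2)
ladder) with subpixel quadratic refinement and 8x8 normalized patch
descriptors sampled at the keypoint's scale; matching is exhaustive
nearest-descriptor search with the Lowe ratio test at 0.75.  Rotation
invariance is deliberately omitted: LED-shifted captures are pure
translations, and orientation estimation would only add noise.

Two robustness measures matter in practice:

* **Iterative residual trim.**  Roughly a few percent of ratio-test
  survivors on fringe-textured images are gross mismatches with residuals
  of tens of pixels.  A single 3x-RMS trim pass cannot remove them — the
  outliers themselves inflate the RMS that defines the cut — so
  `fit_affine()` repeats the trim until no correspondence is dropped.
* **Median-displacement gate.**  Holographic fringes are locally
  periodic, so a minority of matches form a *self-consistent* cluster
  offset by one fringe period (or by the canvas period, for wrapped
  content).  Least squares cannot reject a consistent cluster; since
  LED stacks are near-pure translations, `align_stack()` discards
  matches deviating more than `gate_px = 5` px from the per-pair median
  displacement before fitting.

Mosaic composition warps every tile into the anchor frame (bilinear),
averages overlapping contributions and records a per-pixel weight map;
uncovered pixels are `NA` and flagged invalid, never silently 0.  Mean
blending makes the mosaic independent of stack order to round-off.
Borders are apodized with a separable Tukey window (exactly 1 in the
interior, 0 at the edge, default margin 10%) before the mosaic enters
any further Fourier processing.  The stitch-then-reconstruct order is
deliberate: the mosaic of normalized holograms is reconstructed once,
rather than reconstructing tiles individually.

## 4. Counting and calibration

### Circular Hough transform

Cells in reconstruction amplitudes are dark disks on a bright background
(bright-on-dark images are inverted first via the polarity flag).  After
Gaussian pre-smoothing, pixels with gradient magnitude above
`edge_threshold` vote one radius *up* the gradient for every candidate
radius; votes are pooled per radius, smoothed, and normalized by the
circumference `2*pi*r`, so a score of 1 means roughly the full perimeter
voted.  Centre candidates are local maxima of the best-radius score
above `accumulator_threshold`, accepted greedily by descending score
(ties broken by ascending y, then x) with non-maximum suppression at
`min_dist_px`.  Suppression makes touching cells an intentional
under-count mode rather than a double-count mode.  Detection counts are
monotone non-increasing in the accumulator threshold — asserted as a
property test, since the greedy suppression could plausibly have broken
it.

Default radii bracket the expected cell radius in pixels (0.7x–1.3x of
`2.5 µm / 0.18 µm ≈ 14 px` in the device frame), with
`min_dist = 1.7x` that radius.

### Grid-search tuning

`tune_cht()` evaluates every point of a parameter grid on control images
with known counts and minimizes the mean absolute count error; ties keep
the first point in the deterministic `expand.grid()` iteration order.
Two lessons from building the end-to-end experiment are encoded in the
defaults of `run_dilution_experiment()`: the control set must span the
range (a sparse field at 8 and a dense field at 50 million cells/mL),
because loose edge thresholds only reveal their false-positive votes in
crowded fields; and each grid axis lists its default value first, so a
tie (every point perfect on the controls) resolves to the default
instead of to an arbitrary extreme.

### Concentration and regression

`concentration = count / (fov_area_mm2 * chamber_depth_um * 1e-6)`
cells/mL, exactly linear in the count.  The chamber depth is a required
configuration value (100 µm in the synthetic studies, a settled-layer
depth for a shallow channel); no depth is ever silently assumed.
Calibration regresses *device on reference* — the slope answers "how
does the automated count scale with the true count" — with standard
t-based 95% intervals; the direction is switchable.  On noiseless data
the regression recovers coefficients to 1e-9 (asserted).

### Bar-period measurement

The resolution experiment renders a G7.6 three-bar target (line width
2.19 µm), captures and reconstructs it at the device geometry, and
measures the dominant period of the mean profile across the central bar
rows.  The estimator Hann-windows the mean-subtracted profile, zero-pads
16x, takes the magnitude-spectrum peak with parabolic interpolation, and
excludes a low-frequency guard band of 1.5 cycles per analysis window
where the three-bar burst envelope leaks.  Window and guard were
validated against the closed-form cosine fixture and the clean rendered
bar profile before freezing; a peak below 3x the median spectral floor
raises a no-periodicity error rather than returning a number.  The
analysis segment spans 0.9x the bar-pattern width on each side of the
pattern centre; at canvas 384 px the measured half-period on the
reconstruction is 2.22 µm against the 2.19 µm ground truth.

### Contrast gain — what the simulation can and cannot show

Profile contrast is Weber-style: `(plateau - minimum)/plateau`, with the
plateau estimated as the 0.9 quantile.  The gain of the twin-image-
removed profile over the single-step profile quantifies how much the
iteration deepens the pattern.  A structural note: for a real-valued
contrast hologram of an opaque pattern, single-step back-propagation
recovers almost exactly *half* the amplitude modulation (the twin image
carries the other half), so the single-step contrast sits near 0.5 and
the gain of a perfect restoration saturates near 2 from below; the
noiseless simulation measures about 1.6 at `N = 5`.  Larger gains on real
devices come from partial-coherence and sensor-MTF losses that suppress
the single-step modulation further — physics this simulator deliberately
does not model (section 2).

## 5. Problem sizes, determinism, formats

The package-default study sizes keep every experiment desk-scale: the
resolution experiment uses a 384 px canvas (a 69 µm field at the sample),
and the dilution study uses six levels spanning 0.5–50 million cells/mL
with three replicates on 512 px canvases (92 µm fields, 100 µm chamber
depth, about 0.4–43 expected cells per field).  These are the package's
own choices of scale; the replicate structure (6 x 3) mirrors a routine
bench calibration.

Every stochastic component is seeded and every operation is
deterministic: identical inputs give bit-identical outputs, which the
suite asserts for captures, sidecars and reconstructions.  RNG state is
always restored after use.

On disk: holograms and backgrounds travel as 16-bit TIFF with per-image
amplitude scales recorded in a JSON sidecar; normalized planes,
reconstructions and mosaics as 32-bit float TIFF with an affine range
sidecar (the TIFF writer clamps to [0, 1]); detections and counts as
0-based, origin-top-left CSV; configuration as YAML with unit-suffixed
keys (`_um`, `_mm2`).  YAML rather than TOML is a pragmatic choice — it
round-trips the full config through `read_config(write_config(x))`
identically and needs no extra parser.

## 6. Known limitations

* The propagator is paraxial and periodic; steep-angle and out-of-canvas
  diffraction are folded back rather than lost, and simulation and
  reconstruction share the same kernel (a deliberately "inverse" setup:
  right for validating algorithms, wrong for estimating device physics).
* Partial coherence, sensor MTF and 3D sample structure are not
  modelled; resolution and contrast figures from the simulator are upper
  bounds on what the physical device achieves.
* The feature detector targets translation-dominant stacks; strong
  rotation or scale change between tiles would need an orientation-
  normalized descriptor.
* The circular Hough detector assumes approximately circular, isolated
  cells; heavy clumping is handled only by the under-counting suppression
  rule, and elongated contaminants (e.g. bacilli) are out of scope.
* Multilayer (3D) deconvolution and reconstruct-then-stitch orderings
  are intentionally not implemented.
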