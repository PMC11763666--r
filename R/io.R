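# File formats: 16/32-bit TIFF and PNG images, capture stacks with a JSON
# sidecar, detection/count CSVs.

#' Read a grayscale hologram image
#'
#' Reads TIFF or PNG (by extension) into a numeric matrix.  Integer images
#' are returned on their stored scale in `[0, 1]`; an optional `scale`
#' multiplies back to physical amplitude units (capture stacks record it in
#' their sidecar).
#'
#' @param path File path (`.tif`, `.tiff` or `.png`).
#' @param scale Multiplicative amplitude scale (default 1); ignored when a
#'   `<path>.range.json` sidecar written by the 32-bit float transport is
#'   present.
#' @return A numeric matrix.
#' @export
read_hologram_image <- function(path, scale = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(
    switch(ext,
           tif = , tiff = tiff::readTIFF(path),
           png = png::readPNG(path),
           stop("unsupported image format: .", ext)),
    error = function(e) stop("failed to read image '", path, "': ",
                             conditionMessage(e)))
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  range_file <- paste0(path, ".range.json")
  if (file.exists(range_file)) {
    rg <- jsonlite::read_json(range_file, simplifyVector = TRUE)
    return(img * rg$scale + rg$offset)
  }
  img * scale
}

#' Write a grayscale hologram image
#'
#' Writes a matrix as 16-bit integer TIFF/PNG (values scaled into `[0, 1]`
#' by `scale`, which the caller should record) or as 32-bit floating-point
#' TIFF (`bits = 32`; the transport format for normalized planes and
#' reconstruction amplitudes).  Float output is range-compressed into
#' `[0, 1]` and the affine range is recorded in a `<path>.range.json`
#' sidecar that [read_hologram_image()] applies transparently, so signed
#' contrast images round-trip losslessly to float precision.
#'
#' @param img Numeric matrix.
#' @param path Output path (`.tif`, `.tiff` or `.png`).
#' @param bits 16 (integer) or 32 (float TIFF only).
#' @param scale Divisor bringing `img` into `[0, 1]` for 16-bit output.
#' @return `path`, invisibly.
#' @export
write_hologram_image <- function(img, path, bits = 16L, scale = 1) {
  ext <- tolower(tools::file_ext(path))
  if (bits == 32L) {
    if (!ext %in% c("tif", "tiff"))
      stop("32-bit float output requires a TIFF path")
    offset <- min(img)
    rscale <- max(max(img) - offset, 1e-12)
    tiff::writeTIFF((img - offset) / rscale, path, bits.per.sample = 32L)
    jsonlite::write_json(list(offset = offset, scale = rscale),
                         paste0(path, ".range.json"), auto_unbox = TRUE,
                         digits = NA)
  } else if (bits == 16L) {
    scaled <- pmin(pmax(img / scale, 0), 1)
    if (ext %in% c("tif", "tiff"))
      tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
    else if (ext == "png")
      png::writePNG(scaled, path)
    else stop("unsupported image format: .", ext)
  } else stop("`bits` must be 16 or 32")
  invisible(path)
}

#' Write a multi-LED capture stack with its JSON sidecar
#'
#' Writes each hologram of a stack as a numbered 16-bit TIFF
#' (`capture_000.tif`, ...), the shared background as `background.tif`, and
#' a `sidecar.json` describing the capture: geometry, LED indices, seed,
#' per-image amplitude scales and any ground truth.  The sidecar is the
#' fixture contract consumed by [read_capture_stack()] and the pipeline.
#'
#' @param holograms List of [hologram()] objects (holding amplitude and,
#'   for the first, the background).
#' @param leds Matrix or data frame of LED `(row, col)` indices, one row
#'   per hologram.
#' @param geom The [capture_geometry()] used.
#' @param out_dir Output directory (created if needed).
#' @param seed Seed recorded in the sidecar.
#' @param truth Optional list of ground-truth entries (counts, centres).
#' @return The sidecar path, invisibly.
#' @export
write_capture_stack <- function(holograms, leds, geom, out_dir, seed = NULL,
                                truth = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  leds <- as.matrix(leds)
  n <- length(holograms)
  files <- sprintf("capture_%03d.tif", seq_len(n) - 1L)
  scales <- numeric(n)
  for (k in seq_len(n)) {
    scales[k] <- max(holograms[[k]]$amplitude, 1e-12)
    write_hologram_image(holograms[[k]]$amplitude,
                         file.path(out_dir, files[k]), bits = 16L,
                         scale = scales[k])
  }
  bg <- holograms[[1L]]$background
  bg_scale <- NULL
  if (!is.null(bg)) {
    bg_scale <- max(bg, 1e-12)
    write_hologram_image(bg, file.path(out_dir, "background.tif"),
                         bits = 16L, scale = bg_scale)
  }
  sidecar <- list(
    format = "holocount-capture-stack-v1",
    geometry = list(z1_um = geom$z1_um, z2_um = geom$z2_um,
                    camera_pitch_um = geom$camera_pitch_um,
                    led_pitch_um = geom$led_pitch_um,
                    wavelength_um = geom$wavelength_um),
    files = files,
    leds = lapply(seq_len(n), function(k) as.integer(leds[k, ])),
    amplitude_scales = scales,
    background_file = if (is.null(bg)) NULL else "background.tif",
    background_scale = bg_scale,
    seed = seed,
    truth = truth)
  path <- file.path(out_dir, "sidecar.json")
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a capture stack written by [write_capture_stack()]
#'
#' @param dir Directory containing `sidecar.json` and the TIFFs.
#' @return A list with `holograms` (list of [hologram()], background
#'   attached to each), `leds`, `geometry` (a [capture_geometry()]),
#'   `seed` and `truth`.
#' @export
read_capture_stack <- function(dir) {
  sc_path <- file.path(dir, "sidecar.json")
  if (!file.exists(sc_path)) stop("no sidecar.json in ", dir)
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  g <- sc$geometry
  geom <- capture_geometry(z1_um = g$z1_um, z2_um = g$z2_um,
                           camera_pitch_um = g$camera_pitch_um,
                           led_pitch_um = g$led_pitch_um,
                           wavelength_um = g$wavelength_um)
  bg <- NULL
  if (!is.null(sc$background_file))
    bg <- read_hologram_image(file.path(dir, sc$background_file),
                              scale = sc$background_scale)
  holograms <- lapply(seq_along(sc$files), function(k) {
    amp <- read_hologram_image(file.path(dir, sc$files[k]),
                               scale = sc$amplitude_scales[k])
    hologram(amp, geom$camera_pitch_um, background = bg)
  })
  leds <- sc$leds
  if (is.list(leds)) leds <- do.call(rbind, leds)
  list(holograms = holograms, leds = leds, geometry = geom,
       seed = sc$seed, truth = sc$truth)
}

#' Write detections as CSV
#'
#' Columns `image_id`, `x_px`, `y_px`, `r_px`, `score`.  Coordinates are
#' converted to the 0-based, origin top-left, x-=-column convention used by
#' all on-disk artifacts.
#'
#' @param detections Data frame from [detect_cells()].
#' @param path Output CSV path.
#' @param image_id Identifier recorded with every row.
#' @return `path`, invisibly.
#' @export
write_detections_csv <- function(detections, path, image_id = "image_0") {
  out <- data.frame(image_id = image_id,
                    x_px = detections$x_px - 1,
                    y_px = detections$y_px - 1,
                    r_px = detections$r_px,
                    score = detections$score)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write per-image counts and concentrations as CSV
#'
#' @param counts Data frame with columns `image_id`, `count`,
#'   `concentration_per_ml`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(counts, path) {
  utils::write.csv(counts, path, row.names = FALSE)
  invisible(path)
}
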