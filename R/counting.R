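# Cell detection and counting: gradient-voting circular Hough transform,
# grid-search parameter tuning, and count-to-concentration conversion.

#' Circular Hough transform parameters
#'
#' @param r_min_px,r_max_px Radius search range in pixels
#'   (`0 < r_min_px <= r_max_px`).
#' @param min_dist_px Minimum separation between accepted centres; closer
#'   candidates are suppressed (an intentional under-count mode for
#'   touching cells).
#' @param edge_threshold Gradient-magnitude threshold selecting edge pixels
#'   that cast votes (> 0, in amplitude units per pixel).
#' @param accumulator_threshold Vote threshold (> 0) on the normalized
#'   accumulator score; the score is the vote count divided by the circle
#'   circumference `2*pi*r`, so roughly the fraction of the perimeter that
#'   voted.
#' @param preblur_sigma Gaussian smoothing applied before gradient
#'   computation (pixels).
#' @return An object of class `cht_params`.
#' @export
cht_params <- function(r_min_px = 10, r_max_px = 18, min_dist_px = 20,
                       edge_threshold = 0.05, accumulator_threshold = 0.3,
                       preblur_sigma = 2) {
  if (r_min_px <= 0 || r_max_px < r_min_px)
    stop("need 0 < r_min_px <= r_max_px")
  if (min_dist_px <= 0) stop("`min_dist_px` must be positive")
  if (edge_threshold <= 0 || accumulator_threshold <= 0)
    stop("thresholds must be positive")
  if (preblur_sigma < 0) stop("`preblur_sigma` must be >= 0")
  structure(list(r_min_px = r_min_px, r_max_px = r_max_px,
                 min_dist_px = min_dist_px, edge_threshold = edge_threshold,
                 accumulator_threshold = accumulator_threshold,
                 preblur_sigma = preblur_sigma),
            class = "cht_params")
}

#' Detect circular cells with a circular Hough transform
#'
#' Classic gradient-voting CHT: after Gaussian pre-smoothing, every pixel
#' whose gradient magnitude exceeds `edge_threshold` casts one vote per
#' candidate radius at the position one radius *up* the gradient (towards
#' darker values), which is where the centre of a dark cell on a bright
#' background lies.  Votes are pooled in a per-radius accumulator, smoothed,
#' normalized by circumference, and centre candidates are taken as local
#' maxima of the best-radius score map above `accumulator_threshold`.
#' Candidates are accepted greedily by descending score (ties broken by
#' ascending y then x) with non-maximum suppression at `min_dist_px`.
#'
#' @param img Numeric matrix, a reconstruction amplitude.  With the default
#'   `polarity = "dark"` cells are darker than the background; use
#'   `"bright"` to invert first.
#' @param params A [cht_params()]; `r_max_px` must be smaller than half the
#'   smaller image dimension.
#' @param polarity `"dark"` (default) or `"bright"`.
#' @return Data frame of detections, columns `x_px`, `y_px`, `r_px`,
#'   `score`, sorted by descending score.  Coordinates are 1-based matrix
#'   coordinates (x = column).
#' @export
detect_cells <- function(img, params = cht_params(),
                         polarity = c("dark", "bright")) {
  stopifnot(inherits(params, "cht_params"))
  polarity <- match.arg(polarity)
  if (!is.matrix(img) || !is.numeric(img)) stop("`img` must be a numeric matrix")
  nr <- nrow(img); nc <- ncol(img)
  if (params$r_max_px >= min(nr, nc) / 2)
    stop("`r_max_px` must be smaller than half the smaller image dimension")
  if (polarity == "bright") img <- max(img) - img
  if (params$preblur_sigma > 0)
    img <- as.matrix(EBImage::gblur(img, params$preblur_sigma))
  gx <- (img[, c(2:nc, nc)] - img[, c(1, 1:(nc - 1))]) / 2
  gy <- (img[c(2:nr, nr), ] - img[c(1, 1:(nr - 1)), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  edge <- which(mag > params$edge_threshold)
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      r_px = numeric(0), score = numeric(0))
  if (length(edge) == 0L) return(empty)
  ex <- ((edge - 1L) %/% nr) + 1L
  ey <- ((edge - 1L) %% nr) + 1L
  ux <- gx[edge] / mag[edge]
  uy <- gy[edge] / mag[edge]
  radii <- seq(ceiling(params$r_min_px), floor(params$r_max_px))
  if (length(radii) == 0L) radii <- round((params$r_min_px + params$r_max_px) / 2)
  score_best <- matrix(0, nr, nc)
  r_best <- matrix(radii[1], nr, nc)
  for (r in radii) {
    # vote against the gradient: centres of dark circles are up-gradient
    cx <- as.integer(round(ex - r * ux))
    cy <- as.integer(round(ey - r * uy))
    ok <- cx >= 1L & cx <= nc & cy >= 1L & cy <= nr
    if (!any(ok)) next
    plane <- matrix(tabulate(cy[ok] + (cx[ok] - 1L) * nr, nbins = nr * nc),
                    nr, nc)
    plane <- as.matrix(EBImage::gblur(plane, 1.5)) * (2 * pi * 1.5^2)
    sc <- plane / (2 * pi * r)
    better <- sc > score_best
    score_best[better] <- sc[better]
    r_best[better] <- r
  }
  cand <- which(score_best >= params$accumulator_threshold &
                  score_best >= local_max3(score_best) & score_best > 0)
  if (length(cand) == 0L) return(empty)
  cdf <- data.frame(x_px = ((cand - 1L) %/% nr) + 1L,
                    y_px = ((cand - 1L) %% nr) + 1L,
                    r_px = r_best[cand], score = score_best[cand])
  cdf <- cdf[order(-cdf$score, cdf$y_px, cdf$x_px), , drop = FALSE]
  keep <- logical(0)
  ax <- numeric(0); ay <- numeric(0)
  for (i in seq_len(nrow(cdf))) {
    if (length(ax) == 0L ||
        min(sqrt((ax - cdf$x_px[i])^2 + (ay - cdf$y_px[i])^2)) >=
          params$min_dist_px) {
      ax <- c(ax, cdf$x_px[i]); ay <- c(ay, cdf$y_px[i])
      keep <- c(keep, i)
    }
  }
  out <- cdf[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Grid-search tuning of CHT parameters against labelled counts
#'
#' Evaluates every point of a parameter grid on a set of control images
#' with known counts and returns the point minimizing the mean absolute
#' count error.  The grid is expanded in deterministic lexicographic order
#' (first axis varying fastest, as [expand.grid()] does); ties keep the
#' first point in that order.
#'
#' @param fixtures List of fixtures, each a list with `img` (matrix) and
#'   `true_count`.
#' @param grid Named list of parameter vectors (names as in
#'   [cht_params()]); axes not present keep the values of `base`.
#' @param base A [cht_params()] supplying the non-searched parameters.
#' @param polarity Passed to [detect_cells()].
#' @return A list with `params` (best [cht_params()]), `mae`, `errors`
#'   (per-fixture absolute errors at the best point) and `table` (the full
#'   grid with its mean absolute errors).
#' @export
tune_cht <- function(fixtures, grid, base = cht_params(),
                     polarity = "dark") {
  if (length(fixtures) == 0L) stop("`fixtures` must be non-empty")
  if (length(grid) == 0L) stop("`grid` must be non-empty")
  bad <- setdiff(names(grid), names(unclass(base)))
  if (length(bad)) stop("unknown CHT parameters in grid: ",
                        paste(bad, collapse = ", "))
  tab <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  mae <- numeric(nrow(tab))
  err_at <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    p <- utils::modifyList(unclass(base), as.list(tab[i, , drop = FALSE]))
    p <- do.call(cht_params, p)
    errs <- vapply(fixtures, function(fx) {
      abs(nrow(detect_cells(fx$img, p, polarity)) - fx$true_count)
    }, numeric(1))
    mae[i] <- mean(errs)
    err_at[[i]] <- errs
  }
  best <- which.min(mae)  # first minimum in grid order
  tab$mae <- mae
  list(params = do.call(cht_params,
                        utils::modifyList(unclass(base),
                                          as.list(tab[best, names(grid),
                                                      drop = FALSE]))),
       mae = mae[best], errors = err_at[[best]], table = tab)
}

#' Convert a cell count to a concentration
#'
#' The imaged volume is `fov_area_mm2 * chamber_depth_um * 1e-6` millilitres
#' (1 mm^2 x 1 um = 1e-6 mL), so
#' `concentration = count / volume` in cells/mL.  Exactly linear in `count`.
#'
#' @param count Number of detected cells (>= 0).
#' @param fov_area_mm2 Imaged field-of-view area in mm^2 (> 0).
#' @param chamber_depth_um Depth of the counted liquid layer in um (> 0).
#' @return An object of class `concentration_result` with fields `count`,
#'   `fov_area_mm2`, `chamber_depth_um`, `volume_ml`,
#'   `concentration_per_ml`.
#' @examples
#' to_concentration(1000, fov_area_mm2 = 1, chamber_depth_um = 500)
#' @export
to_concentration <- function(count, fov_area_mm2, chamber_depth_um) {
  if (fov_area_mm2 <= 0 || chamber_depth_um <= 0)
    stop("`fov_area_mm2` and `chamber_depth_um` must be positive")
  if (count < 0) stop("`count` must be >= 0")
  volume_ml <- fov_area_mm2 * chamber_depth_um * 1e-6
  structure(list(count = count, fov_area_mm2 = fov_area_mm2,
                 chamber_depth_um = chamber_depth_um, volume_ml = volume_ml,
                 concentration_per_ml = count / volume_ml),
            class = "concentration_result")
}

#' @export
print.concentration_result <- function(x, ...) {
  cat(sprintf("<concentration_result> %d cells in %.3g mL -> %.4g cells/mL\n",
              x$count, x$volume_ml, x$concentration_per_ml))
  invisible(x)
}
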