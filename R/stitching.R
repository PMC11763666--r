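# Mosaic composition: multi-scale keypoint detection with patch
# descriptors, brute-force ratio-test matching, least-squares affine
# fitting, mean blending with a weight map, and border apodization.

# Vectorized bilinear interpolation. x = column, y = row coordinate (1-based
# pixel centres).  Returns values and an inside mask (0 outside the image).
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  inside <- x >= 1 & x <= nc & y >= 1 & y <= nr
  xc <- pmin(pmax(x, 1), nc)
  yc <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(xc), nc - 1L); y0 <- pmin(floor(yc), nr - 1L)
  fx <- xc - x0; fy <- yc - y0
  i00 <- y0 + (x0 - 1) * nr
  v <- img[i00] * (1 - fx) * (1 - fy) + img[i00 + nr] * fx * (1 - fy) +
    img[i00 + 1] * (1 - fx) * fy + img[i00 + nr + 1] * fx * fy
  list(value = ifelse(inside, v, 0), inside = inside)
}

# 3 x 3 neighbourhood maximum via shifted pmax (replicated borders).
local_max3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  up <- m[c(1, seq_len(nr - 1)), ]; dn <- m[c(seq_len(nr - 1) + 1, nr), ]
  h <- pmax(m, up, dn)
  lf <- h[, c(1, seq_len(nc - 1))]; rt <- h[, c(seq_len(nc - 1) + 1, nc)]
  pmax(h, lf, rt)
}

#' Detect multi-scale keypoints with patch descriptors
#'
#' A compact scale-space detector in the spirit of SIFT: the image is
#' blurred at a geometric ladder of Gaussian scales, difference-of-Gaussian
#' (DoG) responses are formed, and local extrema over space and scale that
#' exceed a contrast threshold become keypoints.  Centres are refined to
#' subpixel precision by a quadratic fit of the DoG response.  Each keypoint
#' carries a 64-dimensional descriptor: an 8 x 8 intensity patch sampled at
#' a spacing proportional to the keypoint scale from the matching blurred
#' image, normalized to zero mean and unit norm (invariant to affine
#' intensity changes; rotation invariance is not needed for LED-shifted
#' captures).
#'
#' @param img Numeric matrix (non-constant).
#' @param max_keypoints Keep at most this many keypoints, strongest first.
#' @param n_scales Number of DoG octave steps (scale factor sqrt(2)).
#' @param sigma0 Base Gaussian scale in pixels.
#' @param contrast_threshold Minimum |DoG| response, on the image
#'   normalized to `[0, 1]`.
#' @return A list with `keypoints` (data frame `x`, `y`, `sigma`,
#'   `response`) and `descriptors` (one row per keypoint).
#' @export
detect_keypoints <- function(img, max_keypoints = 400L, n_scales = 4L,
                             sigma0 = 1.6, contrast_threshold = 0.01) {
  if (!is.matrix(img)) stop("`img` must be a matrix")
  rng <- range(img)
  if (diff(rng) == 0) stop("image is constant; no features to detect")
  img <- (img - rng[1]) / diff(rng)
  sigmas <- sigma0 * sqrt(2)^(0:(n_scales + 1L))
  blurred <- lapply(sigmas, function(s) as.matrix(EBImage::gblur(img, s)))
  dogs <- lapply(seq_len(n_scales + 1L),
                 function(i) blurred[[i + 1L]] - blurred[[i]])
  nr <- nrow(img); nc <- ncol(img)
  kp <- list()
  for (i in seq(2L, n_scales)) {
    d <- dogs[[i]]
    below <- dogs[[i - 1L]]; above <- dogs[[i + 1L]]
    admax <- pmax(local_max3(abs(d)), local_max3(abs(below)),
                  local_max3(abs(above)))
    is_ext <- abs(d) >= admax & abs(d) > contrast_threshold
    is_ext[c(1:8, (nr - 7):nr), ] <- FALSE
    is_ext[, c(1:8, (nc - 7):nc)] <- FALSE
    idx <- which(is_ext)
    if (length(idx) == 0L) next
    ys <- ((idx - 1L) %% nr) + 1L
    xs <- ((idx - 1L) %/% nr) + 1L
    # subpixel refinement: quadratic fit of the DoG plane
    dxx <- d[idx + nr] - 2 * d[idx] + d[idx - nr]
    dyy <- d[idx + 1L] - 2 * d[idx] + d[idx - 1L]
    gx <- (d[idx + nr] - d[idx - nr]) / 2
    gy <- (d[idx + 1L] - d[idx - 1L]) / 2
    ox <- ifelse(dxx != 0, -gx / dxx, 0)
    oy <- ifelse(dyy != 0, -gy / dyy, 0)
    ox <- pmin(pmax(ox, -0.5), 0.5)
    oy <- pmin(pmax(oy, -0.5), 0.5)
    kp[[length(kp) + 1L]] <- data.frame(
      x = xs + ox, y = ys + oy, sigma = sigmas[i], response = abs(d[idx]),
      level = i)
  }
  if (length(kp) == 0L)
    return(list(keypoints = data.frame(x = numeric(0), y = numeric(0),
                                       sigma = numeric(0),
                                       response = numeric(0)),
                descriptors = matrix(0, 0, 64)))
  kp <- do.call(rbind, kp)
  kp <- kp[order(-kp$response, kp$y, kp$x), , drop = FALSE]
  if (nrow(kp) > max_keypoints) kp <- kp[seq_len(max_keypoints), , drop = FALSE]
  # descriptors: 8 x 8 patch at spacing 1.5 * sigma from the blurred level
  offs <- seq(-3.5, 3.5, by = 1)
  desc <- matrix(0, nrow(kp), 64)
  keep <- rep(TRUE, nrow(kp))
  for (r in seq_len(nrow(kp))) {
    s <- 1.5 * kp$sigma[r]
    gx <- kp$x[r] + offs * s
    gy <- kp$y[r] + offs * s
    g <- expand.grid(y = gy, x = gx)
    pv <- bilinear_sample(blurred[[kp$level[r]]], g$x, g$y)$value
    pv <- pv - mean(pv)
    nrm <- sqrt(sum(pv^2))
    if (nrm < 1e-12) keep[r] <- FALSE else desc[r, ] <- pv / nrm
  }
  kp$level <- NULL
  list(keypoints = kp[keep, , drop = FALSE],
       descriptors = desc[keep, , drop = FALSE])
}

#' Match features between two images
#'
#' Detects keypoints on both images and matches descriptors by exhaustive
#' (brute-force) nearest-neighbour search in Euclidean distance, keeping a
#' match only when the nearest distance is below `ratio_threshold` times
#' the second-nearest (Lowe ratio test).  Deterministic for fixed inputs.
#'
#' @param img_a,img_b Numeric matrices (non-constant).
#' @param ratio_threshold Lowe ratio (default 0.75).
#' @param ... Passed to [detect_keypoints()].
#' @return A `correspondence_set`: a data frame with columns `x_a`, `y_a`,
#'   `x_b`, `y_b`, `match_distance`.
#' @section Errors:
#' Fewer than 3 surviving matches raise an insufficient-matches error.
#' @export
match_features <- function(img_a, img_b, ratio_threshold = 0.75, ...) {
  fa <- detect_keypoints(img_a, ...)
  fb <- detect_keypoints(img_b, ...)
  na <- nrow(fa$keypoints); nb <- nrow(fb$keypoints)
  if (na < 3L || nb < 3L || nb < 2L)
    stop("insufficient matches: too few keypoints (", na, ", ", nb, ")")
  # squared Euclidean distances between descriptor rows
  d2 <- outer(rowSums(fa$descriptors^2), rowSums(fb$descriptors^2), "+") -
    2 * fa$descriptors %*% t(fb$descriptors)
  d2[d2 < 0] <- 0
  best <- apply(d2, 1L, function(row) {
    o <- order(row)[1:2]
    c(o[1], sqrt(row[o[1]]), sqrt(row[o[2]]))
  })
  pass <- best[2, ] < ratio_threshold * pmax(best[3, ], 1e-12)
  if (sum(pass) < 3L)
    stop("insufficient matches: only ", sum(pass),
         " correspondences survive the ratio test")
  ia <- which(pass); ib <- best[1, pass]
  out <- data.frame(x_a = fa$keypoints$x[ia], y_a = fa$keypoints$y[ia],
                    x_b = fb$keypoints$x[ib], y_b = fb$keypoints$y[ib],
                    match_distance = best[2, pass])
  class(out) <- c("correspondence_set", class(out))
  out
}

#' Affine transform
#'
#' Coefficients of the planar affine map `x' = a*x + b*y + c`,
#' `y' = d*x + e*y + f` (x = column, y = row, pixel units).
#'
#' @param a,b,c,d,e,f Coefficients; the linear part must be invertible.
#' @return An object of class `affine_transform`.
#' @export
affine_transform <- function(a = 1, b = 0, c = 0, d = 0, e = 1, f = 0) {
  if (abs(a * e - b * d) < 1e-12)
    stop("affine transform is singular (a*e - b*d = 0)")
  structure(list(a = a, b = b, c = c, d = d, e = e, f = f),
            class = "affine_transform")
}

#' @rdname affine_transform
#' @param transform An `affine_transform`.
#' @param x,y Coordinates to map.
#' @export
apply_affine <- function(transform, x, y) {
  stopifnot(inherits(transform, "affine_transform"))
  list(x = transform$a * x + transform$b * y + transform$c,
       y = transform$d * x + transform$e * y + transform$f)
}

#' @rdname affine_transform
#' @param t1,t2 Transforms; the composition applies `t2` first, then `t1`.
#' @export
compose_affine <- function(t1, t2) {
  affine_transform(
    a = t1$a * t2$a + t1$b * t2$d,
    b = t1$a * t2$b + t1$b * t2$e,
    c = t1$a * t2$c + t1$b * t2$f + t1$c,
    d = t1$d * t2$a + t1$e * t2$d,
    e = t1$d * t2$b + t1$e * t2$e,
    f = t1$d * t2$c + t1$e * t2$f + t1$f)
}

#' @rdname affine_transform
#' @export
invert_affine <- function(transform) {
  det <- transform$a * transform$e - transform$b * transform$d
  ia <- transform$e / det; ib <- -transform$b / det
  id <- -transform$d / det; ie <- transform$a / det
  affine_transform(a = ia, b = ib, c = -(ia * transform$c + ib * transform$f),
                   d = id, e = ie, f = -(id * transform$c + ie * transform$f))
}

#' Least-squares affine fit to point correspondences
#'
#' Two independent ordinary-least-squares fits ("bi-linear"): `x_a` on
#' `(x_b, y_b, 1)` and `y_a` on `(x_b, y_b, 1)`, i.e. the returned transform
#' maps image-b coordinates into image-a coordinates.  With `trim` (the
#' default) correspondences whose residual norm exceeds `trim_factor` times
#' the RMS residual are dropped and the fit repeated until no
#' correspondence is dropped; gross feature mismatches would otherwise
#' corrupt the least-squares solution.
#'
#' @param matches A `correspondence_set` (or data frame with `x_a`, `y_a`,
#'   `x_b`, `y_b`), at least 3 non-collinear correspondences.
#' @param trim Apply the one-pass outlier trim.
#' @param trim_factor Residual multiple defining an outlier (default 3).
#' @return An [affine_transform()] with attributes `residual_rms` and
#'   `n_used`.
#' @export
fit_affine <- function(matches, trim = TRUE, trim_factor = 3) {
  m <- as.data.frame(matches)
  if (nrow(m) < 3L) stop("rank error: need at least 3 correspondences")
  fit_once <- function(m) {
    X <- cbind(1, m$x_b, m$y_b)
    if (qr(X)$rank < 3L)
      stop("rank error: correspondences are collinear or degenerate")
    cx <- stats::.lm.fit(X, m$x_a)$coefficients
    cy <- stats::.lm.fit(X, m$y_a)$coefficients
    tr <- affine_transform(a = cx[2], b = cx[3], c = cx[1],
                           d = cy[2], e = cy[3], f = cy[1])
    p <- apply_affine(tr, m$x_b, m$y_b)
    res <- sqrt((p$x - m$x_a)^2 + (p$y - m$y_a)^2)
    list(tr = tr, res = res)
  }
  f1 <- fit_once(m)
  if (trim && nrow(m) > 3L) {
    # repeat the trim until it converges: a single pass is not robust when
    # gross mismatches inflate the RMS enough to shelter smaller outliers
    for (pass in 1:20) {
      rms <- sqrt(mean(f1$res^2))
      keep <- f1$res <= trim_factor * rms
      if (all(keep) || sum(keep) < 3L) break
      m2 <- m[keep, , drop = FALSE]
      f2 <- tryCatch(fit_once(m2), error = function(e) NULL)
      if (is.null(f2)) break
      f1 <- f2; m <- m2
    }
  }
  out <- f1$tr
  attr(out, "residual_rms") <- sqrt(mean(f1$res^2))
  attr(out, "n_used") <- nrow(m)
  out
}

#' Compose a mosaic from transformed images
#'
#' Warps every image into the anchor frame (the frame the transforms map
#' into; conventionally the first image with an identity transform) using
#' bilinear interpolation, and mean-blends overlapping contributions.  The
#' per-pixel contribution count is returned as a weight map; pixels no image
#' reaches are `NA` in the mosaic and `FALSE` in the `valid` mask, never a
#' silent 0.
#'
#' @param stack List of numeric matrices.
#' @param transforms List of [affine_transform()], one per image, mapping
#'   that image's pixel coordinates into the anchor frame.
#' @param blend Blend mode; only `"mean"` is implemented.
#' @return An object of class `mosaic_result`: list with `image`, `weight`,
#'   `valid`, `transforms` and `origin` (anchor-frame coordinate of mosaic
#'   pixel (1, 1)).
#' @section Errors:
#' If the warped footprints do not form a connected overlap graph containing
#' the anchor, a disconnected-mosaic error is raised.
#' @export
compose_mosaic <- function(stack, transforms, blend = "mean") {
  blend <- match.arg(blend, "mean")
  n <- length(stack)
  if (n == 0L) stop("empty stack")
  if (length(transforms) != n)
    stop("need exactly one transform per image")
  boxes <- vector("list", n)
  for (k in seq_len(n)) {
    nr <- nrow(stack[[k]]); nc <- ncol(stack[[k]])
    p <- apply_affine(transforms[[k]], c(1, nc, 1, nc), c(1, 1, nr, nr))
    boxes[[k]] <- c(xmin = min(p$x), xmax = max(p$x),
                    ymin = min(p$y), ymax = max(p$y))
  }
  # overlap connectivity from the anchor (image 1)
  if (n > 1L) {
    overlaps <- function(b1, b2)
      b1["xmin"] <= b2["xmax"] && b2["xmin"] <= b1["xmax"] &&
      b1["ymin"] <= b2["ymax"] && b2["ymin"] <= b1["ymax"]
    reached <- c(TRUE, rep(FALSE, n - 1L))
    repeat {
      grew <- FALSE
      for (k in which(!reached)) for (j in which(reached)) {
        if (overlaps(boxes[[k]], boxes[[j]])) {
          reached[k] <- TRUE; grew <- TRUE; break
        }
      }
      if (!grew) break
    }
    if (!all(reached))
      stop("disconnected mosaic: images ",
           paste(which(!reached), collapse = ", "),
           " do not overlap the anchor set")
  }
  xmin <- floor(min(vapply(boxes, `[[`, 0, "xmin")))
  xmax <- ceiling(max(vapply(boxes, `[[`, 0, "xmax")))
  ymin <- floor(min(vapply(boxes, `[[`, 0, "ymin")))
  ymax <- ceiling(max(vapply(boxes, `[[`, 0, "ymax")))
  W <- xmax - xmin + 1L; H <- ymax - ymin + 1L
  acc <- matrix(0, H, W); wt <- matrix(0, H, W)
  for (k in seq_len(n)) {
    b <- boxes[[k]]
    cols <- max(1L, floor(b["xmin"]) - xmin + 1L):min(W, ceiling(b["xmax"]) - xmin + 1L)
    rows <- max(1L, floor(b["ymin"]) - ymin + 1L):min(H, ceiling(b["ymax"]) - ymin + 1L)
    gx <- rep(cols + xmin - 1L, each = length(rows))
    gy <- rep(rows + ymin - 1L, times = length(cols))
    inv <- invert_affine(transforms[[k]])
    src <- apply_affine(inv, gx, gy)
    sv <- bilinear_sample(stack[[k]], src$x, src$y)
    acc[rows, cols] <- acc[rows, cols] +
      matrix(sv$value, length(rows), length(cols))
    wt[rows, cols] <- wt[rows, cols] +
      matrix(as.numeric(sv$inside), length(rows), length(cols))
  }
  img <- acc / wt
  img[wt == 0] <- NA_real_
  structure(list(image = img, weight = wt, valid = wt > 0,
                 transforms = transforms,
                 origin = c(x = xmin, y = ymin)),
            class = "mosaic_result")
}

#' Chain-align a capture stack
#'
#' Matches each image to its predecessor (the LED raster order), fits an
#' affine transform per pair and composes the chain so every transform maps
#' into the first image's frame.
#'
#' LED-shifted captures differ by near-pure translations, so before
#' fitting, matches whose displacement deviates from the per-pair median
#' displacement by more than `gate_px` are discarded: holographic fringes
#' are locally periodic and produce a minority of self-consistent matches
#' offset by a fringe period, which a least-squares fit cannot reject on
#' its own.
#'
#' @param stack List of numeric matrices.
#' @param ratio_threshold Lowe ratio for [match_features()].
#' @param trim Outlier trim for [fit_affine()].
#' @param gate_px Median-displacement consensus gate in pixels
#'   (`Inf` disables it).
#' @param ... Passed to [match_features()].
#' @return List of [affine_transform()], identity first.
#' @export
align_stack <- function(stack, ratio_threshold = 0.75, trim = TRUE,
                        gate_px = 5, ...) {
  n <- length(stack)
  transforms <- vector("list", n)
  transforms[[1L]] <- affine_transform()
  if (n > 1L) for (k in 2:n) {
    mt <- match_features(stack[[k - 1L]], stack[[k]],
                         ratio_threshold = ratio_threshold, ...)
    if (is.finite(gate_px)) {
      dx <- mt$x_b - mt$x_a
      dy <- mt$y_b - mt$y_a
      keep <- abs(dx - stats::median(dx)) <= gate_px &
        abs(dy - stats::median(dy)) <= gate_px
      if (sum(keep) >= 3L) mt <- mt[keep, , drop = FALSE]
    }
    t_pair <- fit_affine(mt, trim = trim)  # maps image k -> image k-1
    transforms[[k]] <- compose_affine(transforms[[k - 1L]], t_pair)
  }
  transforms
}

#' Apodize image borders
#'
#' Multiplies the image by a separable raised-cosine (Tukey) window that is
#' exactly 1 in the interior and tapers to 0 at the borders over a margin of
#' `margin_fraction` of each dimension.  Suppresses the border artifacts
#' that mosaic composition and FFT-based propagation otherwise amplify.
#'
#' @param img Numeric matrix.
#' @param margin_fraction Taper width as a fraction of each dimension, in
#'   (0, 0.5).
#' @return The windowed image.
#' @export
apodize <- function(img, margin_fraction = 0.1) {
  if (!is.numeric(margin_fraction) || margin_fraction <= 0 ||
      margin_fraction >= 0.5)
    stop("`margin_fraction` must be in (0, 0.5)")
  tukey <- function(n) {
    m <- max(2L, round(margin_fraction * n))
    ramp <- 0.5 * (1 - cos(pi * (seq_len(m) - 1) / (m - 1)))
    c(ramp, rep(1, n - 2L * m), rev(ramp))
  }
  img * outer(tukey(nrow(img)), tukey(ncol(img)))
}
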