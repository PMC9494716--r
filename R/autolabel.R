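#' Configuration for the automatic label-generation pipeline
#'
#' Controls the classical pipeline that turns a single-kind cell image
#' into a training mask: Gaussian smoothing, adaptive Gaussian-weighted
#' thresholding, contour extraction with small-area removal and, for
#' adhesive cells, morphological opening.
#'
#' @param gauss_size Side of the (odd) Gaussian smoothing kernel.
#' @param gauss_sigma Gaussian standard deviation, per row/column
#'   direction (default 0.8).
#' @param window Odd side of the adaptive-threshold window.  The 3x3
#'   default is deliberately local; for cells of known size a window of
#'   `2 * max_radius + 1` is the robust choice (see
#'   [autolabel_config_for()]).
#' @param offset Constant `C` subtracted from the Gaussian-weighted local
#'   mean to form the per-pixel threshold.
#' @param window_sigma Bandwidth of the Gaussian window weights; `NULL`
#'   (default) uses the `0.3 * ((window - 1) / 2 - 1) + 0.8` convention of
#'   mainstream imaging libraries.  Values around `window / 2` give
#'   near-uniform weights, making the local mean an estimate of the
#'   background level rather than of the cell interior.
#' @param polarity `"darker"` if cells are darker than background,
#'   `"lighter"` otherwise.
#' @param min_area Minimum filled contour area in pixels; smaller regions
#'   are discarded as debris.
#' @param morphology Apply morphological opening to split adhesive cells
#'   (recommended for macrophage images).
#' @param morph_size Side of the (odd) structuring element.
#' @param morph_shape `"square"` (full box) or `"disk"` (digital disk of
#'   radius `(morph_size - 1) / 2`).  A disk matched to round cells
#'   leaves their boundaries essentially untouched while still cutting
#'   thin adhesion necks; the square is the classical 3x3 kernel.
#' @return A list of class `autolabel_config`.
#' @export
autolabel_config <- function(gauss_size = 3, gauss_sigma = 0.8,
                             window = 3, offset = 2,
                             window_sigma = NULL,
                             polarity = c("darker", "lighter"),
                             min_area = 25, morphology = FALSE,
                             morph_size = 3,
                             morph_shape = c("square", "disk")) {
  polarity <- match.arg(polarity)
  morph_shape <- match.arg(morph_shape)
  check_odd(gauss_size, "gauss_size")
  check_odd(window, "window")
  check_odd(morph_size, "morph_size")
  stopifnot(gauss_sigma > 0, min_area >= 0)
  structure(list(gauss_size = gauss_size, gauss_sigma = gauss_sigma,
                 window = window, offset = offset,
                 window_sigma = window_sigma, polarity = polarity,
                 min_area = min_area, morphology = morphology,
                 morph_size = morph_size, morph_shape = morph_shape),
            class = "autolabel_config")
}

#' Auto-label configuration matched to a synthetic generator
#'
#' Derives the robust preset for a given scene configuration: threshold
#' window `2 * max_radius + 1` of the target class with near-uniform
#' weights, threshold offset an eighth of the cell--background contrast
#' (comfortably above residual noise of the smoothed image while keeping
#' the detected boundary close to the half-contrast level set), minimum
#' area half the smallest true cell area, and, for macrophages (the
#' adhesive class), morphological opening with a disk structuring
#' element of radius half the minimum cell radius -- the most aggressive
#' disk guaranteed to fit inside every cell, so necks between adherent
#' cells are cut without eroding the cells themselves.
#'
#' @param config A [synth_config()].
#' @param kind `"rbc"` or `"macrophage"`.
#' @return An [autolabel_config()].
#' @export
autolabel_config_for <- function(config, kind = c("rbc", "macrophage")) {
  kind <- match.arg(kind)
  r <- if (kind == "rbc") config$rbc_radius else config$mac_radius
  contrast <- abs(config$bg_mean - max(config$cell_means))
  w <- 2 * ceiling(r[2]) + 1
  autolabel_config(window = w,
                   offset = contrast / 8,
                   window_sigma = w / 2,
                   polarity = config$polarity,
                   min_area = floor(pi * r[1]^2 / 2),
                   morphology = (kind == "macrophage"),
                   morph_size = 2 * floor(r[1] / 2) + 1,
                   morph_shape = "disk")
}

gaussian_kernel_1d <- function(size, sigma) {
  half <- (size - 1) / 2
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian smoothing of an 8-bit image
#'
#' Separable Gaussian convolution with a kernel normalised to sum 1 and
#' symmetric (reflective) border handling; the result is rounded to the
#' nearest integer and clamped to \[0, 255\].
#'
#' @param img Grayscale integer matrix in \[0, 255\].
#' @param size Odd kernel side (default 3).
#' @param sigma Standard deviation per direction (default 0.8).
#' @return Smoothed integer matrix.
#' @export
gaussian_smooth <- function(img, size = 3, sigma = 0.8) {
  validate_gray_image(img)
  check_odd(size, "size")
  stopifnot(sigma > 0)
  k <- gaussian_kernel_1d(size, sigma)
  out <- .sep_conv_reflect(img * 1.0, k)
  matrix(as.integer(clamp8(round_px(out))), nrow(img), ncol(img))
}

# opencv-compatible default sigma for a Gaussian window of side w
adaptive_sigma <- function(w) 0.3 * ((w - 1) * 0.5 - 1) + 0.8

#' Adaptive Gaussian-weighted thresholding
#'
#' The per-pixel threshold is the Gaussian-weighted mean of the window
#' centred on the pixel (reflective borders) minus the offset `C`.  A
#' pixel is foreground iff its intensity is strictly below the threshold
#' (darker polarity) or strictly above it (lighter polarity); ties are
#' background.
#'
#' @param img Grayscale integer matrix.
#' @param window Odd window side (>= 3).
#' @param C Offset subtracted from (darker) or added to (lighter) the
#'   local weighted mean.
#' @param polarity `"darker"` or `"lighter"`.
#' @param sigma Gaussian weighting bandwidth; defaults to
#'   `0.3 * ((window - 1) / 2 - 1) + 0.8`, the convention used by
#'   mainstream imaging libraries.
#' @return Binary integer matrix (1 = foreground).
#' @export
adaptive_threshold <- function(img, window = 3, C = 2,
                               polarity = c("darker", "lighter"),
                               sigma = NULL) {
  validate_gray_image(img)
  polarity <- match.arg(polarity)
  check_odd(window, "window")
  if (window < 3) stop("window must be >= 3", call. = FALSE)
  if (is.null(sigma)) sigma <- adaptive_sigma(window)
  k <- gaussian_kernel_1d(window, sigma)
  wmean <- .sep_conv_reflect(img * 1.0, k)
  fg <- if (polarity == "darker") img < wmean - C else img > wmean + C
  matrix(as.integer(fg), nrow(img), ncol(img))
}

#' Digital disk structuring element
#'
#' @param size Odd side length; the disk radius is `(size - 1) / 2`.
#' @return Logical support matrix.
#' @export
disk_kernel <- function(size) {
  check_odd(size, "size")
  h <- (size - 1) / 2
  d <- outer((-h:h)^2, (-h:h)^2, `+`)
  d <= h^2 + h / 2    # mid-crack radius gives a rounder digital disk
}

as_support <- function(kernel) {
  if (length(kernel) == 1) {
    check_odd(kernel, "kernel size")
    matrix(TRUE, kernel, kernel)
  } else {
    check_odd(nrow(kernel), "kernel rows")
    check_odd(ncol(kernel), "kernel cols")
    kernel != 0
  }
}

#' Grayscale erosion (window minimum)
#'
#' `dst(x, y) = min` over the kernel support of `src(x + x', y + y')`,
#' with the anchor at the kernel centre and replicate border padding.
#' Works on grayscale images and binary masks alike.
#'
#' @param img Numeric matrix.
#' @param kernel Odd kernel side (integer) or a 0/1 support matrix with
#'   odd dimensions; default 3x3 full square.
#' @return Matrix of the same type.
#' @export
erode <- function(img, kernel = 3) {
  s <- as_support(kernel)
  out <- .minmax_filter(img * 1.0, s, TRUE)
  if (is.integer(img)) matrix(as.integer(out), nrow(img), ncol(img)) else out
}

#' Grayscale dilation (window maximum)
#'
#' As [erode()] but taking the window maximum.
#'
#' @inheritParams erode
#' @return Matrix of the same type.
#' @export
dilate <- function(img, kernel = 3) {
  s <- as_support(kernel)
  out <- .minmax_filter(img * 1.0, s, FALSE)
  if (is.integer(img)) matrix(as.integer(out), nrow(img), ncol(img)) else out
}

#' Morphological opening
#'
#' Erosion followed by dilation; removes thin bridges between adhesive
#' cells and protrusions narrower than the structuring element, while
#' leaving smooth shapes essentially unchanged (opening is idempotent).
#'
#' @inheritParams erode
#' @export
open_morph <- function(img, kernel = 3) {
  dilate(erode(img, kernel), kernel)
}

#' Extract outer contours of a binary mask
#'
#' One contour per 8-connected foreground component: the closed outermost
#' border traced clockwise from the component's top-left-most pixel
#' (border following); internal holes are ignored.  Contours are returned
#' in raster order of their starting pixel.
#'
#' @param mask Binary integer matrix.
#' @return List of contours; each is a list with `points` (n x 2 matrix
#'   of 1-based (row, col) boundary coordinates), `closed` (TRUE) and
#'   `area` (pixel area enclosed by the boundary, holes filled).
#' @export
find_contours <- function(mask) {
  storage.mode(mask) <- "integer"
  nr <- nrow(mask)
  lab <- .label_components(mask)
  w <- which(lab > 0L)
  if (!length(w)) return(list())
  comp_idx <- split(w, lab[w])
  # all work restricted to each component's bounding box
  out <- lapply(comp_idx, function(idx) {
    r <- ((idx - 1L) %% nr) + 1L
    c <- ((idx - 1L) %/% nr) + 1L
    r0 <- min(r); c0 <- min(c)
    sub <- matrix(FALSE, max(r) - r0 + 1L, max(c) - c0 + 1L)
    sub[cbind(r - r0 + 1L, c - c0 + 1L)] <- TRUE
    pts <- .trace_boundary(sub)
    area <- sum(.fill_holes(sub))
    pts[, 1] <- pts[, 1] + r0 - 1L
    pts[, 2] <- pts[, 2] + c0 - 1L
    list(points = pts, closed = TRUE, area = area)
  })
  names(out) <- NULL
  out
}

# rasterize a closed boundary and fill it from outside (holes closed);
# returns 1-based pixel indices of the filled region
contour_fill <- function(pts, nr, nc) {
  if (any(pts[, 1] < 1 | pts[, 1] > nr | pts[, 2] < 1 | pts[, 2] > nc))
    stop("contour point out of bounds for a ", nr, " x ", nc, " mask",
         call. = FALSE)
  r0 <- min(pts[, 1]); c0 <- min(pts[, 2])
  canvas <- matrix(FALSE, max(pts[, 1]) - r0 + 1L, max(pts[, 2]) - c0 + 1L)
  canvas[cbind(pts[, 1] - r0 + 1L, pts[, 2] - c0 + 1L)] <- TRUE
  filled <- which(.fill_holes(canvas))
  fr <- ((filled - 1L) %% nrow(canvas)) + r0
  fc <- ((filled - 1L) %/% nrow(canvas)) + c0
  cbind(fr, fc)
}

#' Drop contours below a minimum filled area
#'
#' @param contours List of contours from [find_contours()].
#' @param min_area Minimum filled area in pixels.
#' @return Filtered list, original order preserved.
#' @export
filter_small <- function(contours, min_area) {
  stopifnot(min_area >= 0)
  Filter(function(ct) ct$area >= min_area, contours)
}

#' Fill contours into a class mask
#'
#' Interior and boundary of every contour are set to `class_value`,
#' everything else to 0.  Holes enclosed by a contour are filled.
#'
#' @param contours List of contours.
#' @param shape Length-2 output dimensions (rows, cols).
#' @param class_value Class index to write (>= 1).
#' @return Integer class mask.
#' @export
fill_contours <- function(contours, shape, class_value = 1) {
  stopifnot(class_value >= 1)
  out <- matrix(0L, shape[1], shape[2])
  for (ct in contours)
    out[contour_fill(ct$points, shape[1], shape[2])] <-
      as.integer(class_value)
  out
}

#' Automatically generate a training mask for a single-kind cell image
#'
#' Runs the full label-generation pipeline: Gaussian smoothing, adaptive
#' thresholding, contour extraction, small-area removal, optional
#' morphological opening (applied to the filled binary mask, after which
#' contours are re-extracted and re-filtered), and contour filling with
#' the requested class value.
#'
#' @param img Grayscale integer matrix.
#' @param config An [autolabel_config()].
#' @param class_value Class index written into the mask (1 = RBC,
#'   2 = macrophage).
#' @return Integer class mask of the same shape as `img`.
#' @export
autolabel_image <- function(img, config = autolabel_config(),
                            class_value = 1) {
  stopifnot(inherits(config, "autolabel_config"))
  sm <- gaussian_smooth(img, config$gauss_size, config$gauss_sigma)
  bin <- adaptive_threshold(sm, config$window, config$offset,
                            config$polarity, sigma = config$window_sigma)
  cts <- filter_small(find_contours(bin), config$min_area)
  if (config$morphology) {
    se <- if (config$morph_shape == "disk") disk_kernel(config$morph_size)
          else config$morph_size
    filled <- fill_contours(cts, dim(img), 1)
    opened <- open_morph(filled, se)
    cts <- filter_small(find_contours(opened), config$min_area)
  }
  fill_contours(cts, dim(img), class_value)
}
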