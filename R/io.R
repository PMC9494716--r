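#' Read a microscopy image as an 8-bit grayscale matrix
#'
#' Reads a PNG or TIFF image and returns an integer matrix of intensities
#' in \[0, 255\], indexed (row, col) with the origin at the top-left.
#' Colour images are converted to single-channel luminance; an alpha
#' channel, if present, is dropped.
#'
#' @param path Path to a PNG or TIFF file.
#' @param rgb_weights Length-3 luminance weights for the RGB-to-gray
#'   conversion.  Defaults to the Rec. 601 luma coefficients
#'   (0.299, 0.587, 0.114).
#' @return Integer matrix with values in \[0, 255\].
#' @examples
#' img <- matrix(as.integer(c(0, 128, 255, 64)), 2, 2)
#' p <- tempfile(fileext = ".png")
#' write_image(img, p)
#' identical(read_image(p), img)
#' @export
read_image <- function(path, rgb_weights = c(0.299, 0.587, 0.114)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  a <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the 'tiff' package", call. = FALSE)
    tiff::readTIFF(path)
  } else if (ext == "png") {
    png::readPNG(path)
  } else {
    stop("unsupported image format: '", ext, "' (PNG or TIFF expected)",
         call. = FALSE)
  }
  if (length(dim(a)) == 3) {
    nch <- dim(a)[3]
    a <- if (nch >= 3) {
      rgb_weights[1] * a[, , 1] + rgb_weights[2] * a[, , 2] +
        rgb_weights[3] * a[, , 3]
    } else {
      a[, , 1]
    }
  }
  m <- matrix(as.integer(clamp8(round_px(a * 255))), nrow(a), ncol(a))
  validate_gray_image(m, "decoded image")
  m
}

#' Write an 8-bit grayscale image to PNG
#'
#' @param img Integer matrix with values in \[0, 255\].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_image <- function(img, path) {
  validate_gray_image(img)
  png::writePNG(img / 255, path)
  invisible(path)
}

#' Read a class mask from an 8-bit PNG
#'
#' Masks are stored as plain 8-bit grayscale PNGs whose pixel value IS the
#' class index (0 = background, 1 = RBC, 2 = macrophage).  Every pixel is
#' validated against `{0, ..., num_classes - 1}`.
#'
#' @param path Path to the mask PNG.
#' @param num_classes Number of classes including background (default 3).
#' @return Integer matrix of class indices.
#' @export
read_mask <- function(path, num_classes = 3) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  m <- matrix(as.integer(round_px(a * 255)), nrow(a), ncol(a))
  validate_class_mask(m, num_classes, "mask file")
  m
}

#' Write a class mask as a lossless 8-bit PNG
#'
#' The class index is stored verbatim as the pixel value (no palette),
#' so `read_mask(write_mask(m))` is bit-exact.
#'
#' @param mask Integer matrix of class indices in \[0, 255\].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (!is.matrix(mask) || anyNA(mask) || min(mask) < 0 || max(mask) > 255)
    stop("mask must be a matrix with values in [0, 255]", call. = FALSE)
  png::writePNG(mask / 255, path)
  invisible(path)
}

#' Assemble a dataset split from image and mask directories
#'
#' Discovers PNG/TIFF files, pairs images with masks by file name, and
#' returns a deterministic (lexicographically sorted) manifest so splits
#' are reproducible across platforms.
#'
#' @param image_dir Directory of images.
#' @param mask_dir Optional directory of masks; when given, every image
#'   must have a mask with the same base name (extension `.png`).
#' @param role One of `"train"`, `"val"`, `"test"`.
#' @return Data frame with columns `image`, `mask` (NA when absent) and
#'   `role`, ordered by image file name.
#' @export
dataset_split <- function(image_dir, mask_dir = NULL,
                          role = c("train", "val", "test")) {
  role <- match.arg(role)
  imgs <- sort(list.files(image_dir, pattern = "\\.(png|tif|tiff)$",
                          ignore.case = TRUE, full.names = TRUE),
               method = "radix")
  if (!length(imgs)) stop("no images found in ", image_dir, call. = FALSE)
  masks <- rep(NA_character_, length(imgs))
  if (!is.null(mask_dir)) {
    masks <- file.path(mask_dir,
                       paste0(tools::file_path_sans_ext(basename(imgs)),
                              ".png"))
    missing <- !file.exists(masks)
    if (any(missing))
      stop("missing mask(s) for: ",
           paste(basename(imgs[missing]), collapse = ", "), call. = FALSE)
  }
  data.frame(image = imgs, mask = masks, role = role,
             stringsAsFactors = FALSE)
}
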