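#' Grayscale image container
#'
#' An 8-bit grayscale raster with an optional physical calibration.  The
#' coordinate convention used throughout the package is fixed here:
#' coordinates are 0-based, `x` indexes columns and grows rightward, `y`
#' indexes rows and grows downward, the origin is the top-left pixel.
#' Pixel `(x, y)` lives at `pixels[y + 1, x + 1]` of the underlying
#' row-by-column matrix.
#'
#' @param pixels integer matrix (rows = image height, columns = width)
#'   with values in `[0, 255]`.
#' @param spacing_cm optional numeric of length 1 or 2 giving the physical
#'   size of one pixel in cm.  A length-2 value is `c(x, y)`; a scalar is
#'   used for both axes.  Must be strictly positive.
#' @return An object of class `gray_image` with fields `pixels` and
#'   `spacing_cm` (`NULL` when uncalibrated).
#' @export
gray_image <- function(pixels, spacing_cm = NULL) {
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("`pixels` must be a non-empty matrix", call. = FALSE)
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 255))
    stop("pixel intensities must lie in [0, 255]", call. = FALSE)
  storage.mode(pixels) <- "integer"
  if (!is.null(spacing_cm)) {
    spacing_cm <- as.numeric(spacing_cm)
    if (length(spacing_cm) == 1L) spacing_cm <- c(spacing_cm, spacing_cm)
    if (length(spacing_cm) != 2L || anyNA(spacing_cm) || any(spacing_cm <= 0))
      stop("`spacing_cm` must be strictly positive on both axes", call. = FALSE)
    names(spacing_cm) <- c("x", "y")
  }
  structure(list(pixels = pixels, spacing_cm = spacing_cm),
            class = "gray_image")
}

#' Binary image container
#'
#' Same raster convention as [gray_image()], restricted to the two values
#' 0 (background) and 255 (foreground).
#'
#' @param pixels matrix containing only 0 and 255 (logical matrices are
#'   accepted and mapped to 0/255).
#' @return An object of class `c("binary_image", "gray_image")`.
#' @export
binary_image <- function(pixels) {
  if (is.logical(pixels)) {
    p <- pixels
    storage.mode(p) <- "integer"
    pixels <- p * 255L
  }
  if (!all(pixels == 0L | pixels == 255L))
    stop("a binary image may contain only the values 0 and 255", call. = FALSE)
  img <- gray_image(pixels)
  class(img) <- c("binary_image", class(img))
  img
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<%s> %d x %d px", class(x)[1L], img_width(x), img_height(x)))
  if (!is.null(x$spacing_cm))
    cat(sprintf(", %.4g x %.4g cm/px", x$spacing_cm[["x"]], x$spacing_cm[["y"]]))
  cat("\n")
  invisible(x)
}

#' Image dimensions
#' @param img a [gray_image()].
#' @return Width or height in pixels.
#' @export
img_width <- function(img) ncol(img$pixels)

#' @rdname img_width
#' @export
img_height <- function(img) nrow(img$pixels)

# logical foreground mask of a binary image
fg_mask <- function(bin) bin$pixels == 255L

#' Rectangular region of interest
#'
#' Pixel-aligned rectangle in the package's 0-based convention, half-open
#' on both axes: the ROI covers columns `x0 .. x1 - 1` and rows
#' `y0 .. y1 - 1`.
#'
#' @param x0,y0 top-left corner (inclusive).
#' @param x1,y1 bottom-right corner (exclusive).
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(x0, y0, x1, y1) {
  v <- c(x0 = x0, y0 = y0, x1 = x1, y1 = y1)
  if (anyNA(v) || any(v != round(v)))
    stop("ROI coordinates must be integers", call. = FALSE)
  if (x0 < 0 || y0 < 0 || x0 >= x1 || y0 >= y1)
    stop("ROI must satisfy 0 <= x0 < x1 and 0 <= y0 < y1", call. = FALSE)
  structure(as.list(as.integer(v)), names = names(v), class = "roi_spec")
}

#' Crop a region of interest
#'
#' @param img a [gray_image()].
#' @param roi a [roi_spec()], or a numeric vector `c(x0, y0, x1, y1)`.
#' @return A new image of size `(x1 - x0) x (y1 - y0)`; pixel `(0, 0)` of
#'   the output is pixel `(x0, y0)` of the input.  Physical spacing is
#'   preserved.
#' @export
crop_roi <- function(img, roi) {
  if (!inherits(roi, "roi_spec")) roi <- do.call(roi_spec, as.list(roi))
  if (roi$x1 > img_width(img) || roi$y1 > img_height(img))
    stop("ROI exceeds image bounds", call. = FALSE)
  out <- img$pixels[(roi$y0 + 1L):roi$y1, (roi$x0 + 1L):roi$x1, drop = FALSE]
  res <- gray_image(out, img$spacing_cm)
  if (inherits(img, "binary_image")) res <- binary_image(res$pixels)
  res
}

#' Read a PNG or TIFF image as 8-bit grayscale
#'
#' Color input is converted with the ITU-R BT.601 luma weights
#' `0.299 R + 0.587 G + 0.114 B` (any alpha channel is ignored), then
#' rounded half-up to an integer intensity.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param spacing_cm optional calibration forwarded to [gray_image()]
#'   (PNG/TIFF carry no physical spacing).
#' @return A [gray_image()].
#' @export
read_image <- function(path, spacing_cm = NULL) {
  if (!nzchar(path) || !file.exists(path))
    stop("cannot read image: file not found: '", path, "'", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' (use PNG or TIFF)",
         call. = FALSE))
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3L] >= 3L) {
      arr <- 0.299 * arr[, , 1L] + 0.587 * arr[, , 2L] + 0.114 * arr[, , 3L]
    } else {
      arr <- arr[, , 1L]
    }
  }
  gray_image(round_half_up(arr * 255), spacing_cm)
}

#' Write an image as 8-bit grayscale PNG or TIFF
#'
#' The round trip `write_image()` then [read_image()] reproduces pixels
#' exactly.
#'
#' @param img a [gray_image()].
#' @param path destination path (`.png`, `.tif`, `.tiff`); the directory
#'   must exist.
#' @return The path, invisibly.
#' @export
write_image <- function(img, path) {
  if (!dir.exists(dirname(path)))
    stop("cannot write image: directory does not exist: '",
         dirname(path), "'", call. = FALSE)
  m <- img$pixels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(m, path),
    tif = ,
    tiff = tiff::writeTIFF(m, path, bits.per.sample = 8L),
    stop("unsupported image format '.", ext, "' (use PNG or TIFF)",
         call. = FALSE))
  invisible(path)
}

#' Mirror an image left-right
#'
#' Used by the side-flip covariance checks: column `x` maps to
#' `width - 1 - x`.
#'
#' @param img a [gray_image()] or [binary_image()].
#' @return The mirrored image of the same class.
#' @export
mirror_image <- function(img) {
  out <- img$pixels[, rev(seq_len(ncol(img$pixels))), drop = FALSE]
  if (inherits(img, "binary_image")) return(binary_image(out))
  gray_image(out, img$spacing_cm)
}
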