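#' Intensity histogram
#'
#' @param img a [gray_image()].
#' @return Integer vector of length 256; element `i + 1`, named `i`,
#'   counts the pixels of intensity exactly `i`.  Counts sum to
#'   `width * height`.
#' @export
intensity_histogram <- function(img) {
  h <- tabulate(as.vector(img$pixels) + 1L, nbins = 256L)
  names(h) <- 0:255
  h
}

#' Ends-in search contrast stretching
#'
#' Linear min-max normalization with clamping at both ends: intensities
#' at or below `min_in` map to 0, at or above `max_in` map to 255, and
#' the interior is mapped by `255 * (G - min_in) / (max_in - min_in)`
#' with half-up rounding.  The mapping is monotone non-decreasing, so
#' the relative shape of the intensity distribution is preserved --
#' which is why this enhancement is preferred over smoothing filters for
#' speckled sonograms.
#'
#' In auto mode (the default) `min_in`/`max_in` are the image's own
#' minimum and maximum, so the output of a non-constant image attains
#' both 0 and 255.
#'
#' @param img a [gray_image()].
#' @param min_in,max_in stretch ends; both `NULL` for auto mode.
#' @return A [gray_image()] with the same dimensions and spacing.
#'   A constant image (auto mode) is returned unchanged with a warning,
#'   since the normalization is undefined there.
#' @export
ends_in_stretch <- function(img, min_in = NULL, max_in = NULL) {
  g <- img$pixels
  if (is.null(min_in)) min_in <- min(g)
  if (is.null(max_in)) max_in <- max(g)
  if (min_in > max_in || min_in < 0 || max_in > 255)
    stop("stretch ends must satisfy 0 <= min_in <= max_in <= 255",
         call. = FALSE)
  if (min_in == max_in) {
    warning("constant stretch interval; image returned unchanged")
    return(img)
  }
  p <- round_half_up(255 * (g - min_in) / (max_in - min_in))
  p[g <= min_in] <- 0L
  p[g >= max_in] <- 255L
  gray_image(p, img$spacing_cm)
}
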