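#' Average binarization
#'
#' Thresholds at the mean intensity of the image: pixels at or above the
#' mean become foreground (255), the rest background (0).  On a constant
#' image every pixel equals the mean and the whole image is foreground.
#'
#' @param img a [gray_image()].
#' @return A [binary_image()].
#' @export
average_binarize <- function(img) {
  binary_image(img$pixels >= mean(img$pixels))
}

#' Otsu binarization
#'
#' Chooses the threshold `T` maximizing the between-class variance of
#' the 256-bin intensity histogram (the smallest maximizer on ties);
#' pixels strictly above `T` become foreground.  Kept as the standard
#' bimodal baseline against which the fuzzy-sigma binarizer is compared:
#' near the DCF the histogram is not bimodal, which is exactly where
#' Otsu's assumption breaks down.
#'
#' @param img a [gray_image()] with at least two distinct intensities.
#' @return A [binary_image()]; the chosen threshold is attached as
#'   attribute `"threshold"`.
#' @export
otsu_binarize <- function(img) {
  h <- tabulate(as.vector(img$pixels) + 1L, nbins = 256L)
  if (sum(h > 0L) < 2L)
    stop("Otsu binarization is undefined for a constant image",
         call. = FALSE)
  n <- sum(h)
  lev <- 0:255
  w0 <- cumsum(h)                 # class {intensity <= T}
  s0 <- cumsum(h * lev)
  total <- s0[256L]
  w1 <- n - w0
  mu0 <- ifelse(w0 > 0, s0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (total - s0) / w1, 0)
  sigma_b <- w0 * w1 * (mu0 - mu1)^2
  sigma_b[w0 == 0 | w1 == 0] <- -Inf
  t_best <- which.max(sigma_b) - 1L
  out <- binary_image(img$pixels > t_best)
  attr(out, "threshold") <- t_best
  out
}

#' Fuzzy sigma binarization parameters
#'
#' Derives the support of the sigma-shaped fuzzy membership function
#' from the image's own intensity extremes.  With `p_min`/`p_max` the
#' lowest/highest intensity and `p_mid` their average, the derivation
#' runs in four steps:
#'
#' 1. `p_min_f = p_mid - p_min`, `p_max_f = p_max - p_mid`;
#' 2. `p_mid_f = 255 - p_mid` when `p_mid > p_min + 0.75 (p_max - p_min)`
#'    (compensating an overly brightly filmed image), else
#'    `p_mid_f = p_mid`;
#' 3. the half-width `beta` is picked by a nested conditional that
#'    amounts to `min(p_mid_f, p_max_f)` or `min(p_mid_f, p_min_f)`
#'    depending on which side dominates (implemented verbatim as the
#'    nested conditional; see the test suite for the documented
#'    equivalence);
#' 4. the normalized interval is `[p_mid - beta, p_mid + beta]`.
#'
#' A constant image yields `beta = 0` and the membership degenerates to
#' a step at `p_mid`.
#'
#' @param img a [gray_image()], or `NULL` when `p_min`/`p_max` are given
#'   directly (handy for tracing the derivation).
#' @param alpha_cut membership cut in `[0, 1]` stored with the
#'   parameters; 0.5 by default (no prior preference).
#' @param p_min,p_max intensity extremes, overriding `img`.
#' @return An object of class `fuzzy_params` with fields `p_min`,
#'   `p_max`, `p_mid`, `p_min_f`, `p_max_f`, `p_mid_f`, `beta`,
#'   `p_min_new`, `p_max_new`, `alpha_cut`.
#' @export
fuzzy_sigma_params <- function(img = NULL, alpha_cut = 0.5,
                               p_min = NULL, p_max = NULL) {
  if (is.null(p_min) || is.null(p_max)) {
    if (is.null(img))
      stop("either `img` or both `p_min` and `p_max` are required",
           call. = FALSE)
    p_min <- min(img$pixels)
    p_max <- max(img$pixels)
  }
  if (!is.numeric(alpha_cut) || length(alpha_cut) != 1L ||
      is.na(alpha_cut) || alpha_cut < 0 || alpha_cut > 1)
    stop("`alpha_cut` must be a single value in [0, 1]", call. = FALSE)
  if (p_min > p_max)
    stop("`p_min` must not exceed `p_max`", call. = FALSE)
  p_mid <- (p_min + p_max) / 2

  # Step 1
  p_min_f <- p_mid - p_min
  p_max_f <- p_max - p_mid
  # Step 2: bright-image compensation at three quarters of the contrast
  p_mid_f <- if (p_mid > p_min + 0.75 * (p_max - p_min)) 255 - p_mid else p_mid
  # Step 3: verbatim nested conditional selecting the half-width
  beta <- if (p_mid_f > p_max_f) {
    if (p_min_f > p_mid_f) p_mid_f else p_min_f
  } else {
    if (p_max_f > p_mid_f) p_mid_f else p_max_f
  }
  # Step 4
  structure(list(p_min = p_min, p_max = p_max, p_mid = p_mid,
                 p_min_f = p_min_f, p_max_f = p_max_f, p_mid_f = p_mid_f,
                 beta = beta,
                 p_min_new = p_mid - beta, p_max_new = p_mid + beta,
                 alpha_cut = alpha_cut),
            class = "fuzzy_params")
}

#' Sigma-shaped fuzzy membership degree
#'
#' Membership of an intensity in the bright (foreground) class: 0 at or
#' below `p_min_new`, rising linearly to 1 at `p_mid`, and 1 above.
#' When `beta = 0` (constant image) the ramp collapses to a step at
#' `p_mid`: 0 below, 1 at or above.
#'
#' @param p intensity value(s).
#' @param params a [fuzzy_sigma_params()] object.
#' @return Membership degree(s) in `[0, 1]`, non-decreasing in `p`.
#' @export
fuzzy_membership <- function(p, params) {
  stopifnot(inherits(params, "fuzzy_params"))
  lo <- params$p_min_new
  mid <- params$p_mid
  if (params$beta == 0 || mid <= lo) {
    return(as.numeric(p >= mid))
  }
  u <- (p - lo) / (mid - lo)
  u[p <= lo] <- 0
  u[p >= mid] <- 1
  u
}

#' Fuzzy sigma binarization
#'
#' Binarizes by cutting the sigma membership at `alpha_cut`: a pixel
#' becomes foreground iff its membership degree is at least the cut.
#' Because the support is derived from the image's own contrast, dim but
#' locally bright structures (such as cervical vertebra margins in a
#' low-contrast sonogram) are retained where a global mean threshold
#' would drop them.
#'
#' @param img a [gray_image()].
#' @param alpha_cut membership cut in `[0, 1]`; default 0.5.
#' @return A [binary_image()]; the derived parameters are attached as
#'   attribute `"fuzzy_params"`.
#' @export
fuzzy_sigma_binarize <- function(img, alpha_cut = 0.5) {
  params <- fuzzy_sigma_params(img, alpha_cut = alpha_cut)
  u <- fuzzy_membership(img$pixels, params)
  out <- binary_image(matrix(u >= alpha_cut, nrow = nrow(img$pixels)))
  attr(out, "fuzzy_params") <- params
  out
}
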