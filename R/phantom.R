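#' Parameters of the synthetic craniocervical sonogram phantom
#'
#' The phantom emulates the scene the pipeline is built for: a bright
#' skin line, the dark sternocleidomastoid (SCM) band wrapped in bright
#' fascia, a dark blood vessel between the two muscles, the dark Deep
#' Cervical Flexor (DCF) band wrapped in its own bright fascia sheath,
#' and three bright cervical vertebra echoes with an acoustic shadow
#' beneath, all over a dark tissue background.  Multiplicative unit-mean
#' speckle (gamma distributed) followed by Gaussian blur gives the image
#' its B-mode texture and the characteristic intensity histogram skewed
#' toward zero.  Each vertebra echo is drawn as a bright core inside a
#' dimmer halo whose intensity sits between the global-mean threshold
#' and the fuzzy-sigma cut, reproducing the low-contrast regime in which
#' the fuzzy binarizer retains vertebra pixels that mean thresholding
#' drops.
#'
#' All geometry is in pixels of an `800 x 600` image with a default
#' calibration of 0.01 cm/px; positions of the DCF scene are relative to
#' the default ROI.  `thickness_cm` is the outer fascia-to-fascia
#' vertical extent of the DCF sheath; when `NULL` it is drawn uniformly
#' from `thickness_range_cm` using the phantom seed.
#'
#' @param seed integer seed making the phantom fully reproducible.
#' @param thickness_cm fixed DCF thickness, or `NULL` to draw one.
#' @param thickness_range_cm range for the drawn thickness (cm).
#' @param speckle_var variance of the unit-mean multiplicative speckle
#'   (0 disables it).
#' @param blur_sigma Gaussian blur standard deviation in pixels
#'   (0 disables it).
#' @param shift_right place the vertebra row fully right of the ROI
#'   center (the scenario in which the leftmost vertebra is off-scene
#'   and distance-weighted restoration triggers).
#' @param ... overrides for the remaining geometry/intensity fields; see
#'   the source for the full list.
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(seed = 1L, thickness_cm = NULL,
                           thickness_range_cm = c(0.6, 1.4),
                           speckle_var = 0.02, blur_sigma = 1,
                           shift_right = FALSE, ...) {
  p <- list(
    width = 800L, height = 600L, spacing_cm = c(x = 0.01, y = 0.01),
    seed = as.integer(seed),
    roi = c(144L, 150L, 656L, 450L),
    scm_roi = c(144L, 26L, 656L, 148L),
    thickness_cm = thickness_cm,
    thickness_range_cm = thickness_range_cm,
    # intensity means before speckle/blur
    i_background = 35, i_dcf = 28, i_fascia = 195,
    i_vert_core = 165, i_vert_margin = 72, i_shadow = 18,
    i_skin = 200, i_scm = 40, i_vessel = 15,
    # DCF sheath geometry (ROI-relative)
    fascia_px = 16L, sheath_inset_px = 4L, sheath_top_px = 14L,
    bow_px = 8, cap_px = 16L,
    # vertebrae (ROI-relative)
    vert_count = 3L, vert_core_w = 115, vert_core_h = 98,
    vert_margin_px = 14, vert_first_left = 56L, vert_gap_px = 10L,
    vert_offset_px = 12L, shadow_px = 28L,
    # superficial anatomy (image coordinates)
    skin_rows = c(6L, 24L), scm_outer_top = 30L, scm_thickness_px = 70L,
    scm_fascia_px = 7L, scm_bow_px = 6,
    vessel_center = c(400, 127), vessel_axes = c(70, 14),
    speckle_var = speckle_var, blur_sigma = blur_sigma,
    shift_right = isTRUE(shift_right))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(p))
  if (length(unknown))
    stop("unknown phantom parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  p[names(dots)] <- dots
  structure(p, class = "phantom_params")
}

# power-4 superellipse (rounded rectangle) as a full-size logical mask
superellipse_mask <- function(h, w, cx, cy, half_w, half_h, p = 4) {
  full <- matrix(FALSE, h, w)
  r0 <- max(0, floor(cy - half_h)); r1 <- min(h - 1, ceiling(cy + half_h))
  c0 <- max(0, floor(cx - half_w)); c1 <- min(w - 1, ceiling(cx + half_w))
  if (r0 > r1 || c0 > c1) return(full)
  yy <- r0:r1; xx <- c0:c1
  m <- outer(abs((yy - cy) / half_h)^p, abs((xx - cx) / half_w)^p, `+`) <= 1
  full[yy + 1L, xx + 1L] <- m
  full
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

# draw a fascia-wrapped band ("sheath"): bowed outer boundaries with
# filled fascia ring and darker interior; returns updated canvas plus
# the outer boundary rows per column and the band mask
draw_sheath <- function(canvas, x_cols, y_upper, thickness, fascia_px,
                        cap_px, i_fascia, i_interior) {
  y_lower <- y_upper + thickness - 1L
  mask <- matrix(FALSE, nrow(canvas), ncol(canvas))
  ncols <- length(x_cols)
  for (j in seq_len(ncols)) {
    cx <- x_cols[j] + 1L
    rows <- (y_upper[j] + 1L):(y_lower[j] + 1L)
    is_cap <- j <= cap_px || j > ncols - cap_px
    if (is_cap) {
      canvas[rows, cx] <- i_fascia
    } else {
      canvas[rows, cx] <- i_interior
      canvas[(y_upper[j] + 1L):(y_upper[j] + fascia_px), cx] <- i_fascia
      canvas[(y_lower[j] + 2L - fascia_px):(y_lower[j] + 1L), cx] <- i_fascia
    }
    mask[rows, cx] <- TRUE
  }
  list(canvas = canvas, mask = mask, y_upper = y_upper, y_lower = y_lower)
}

#' Generate a synthetic craniocervical sonogram with ground truth
#'
#' Draws the layered scene described in [phantom_params()], records the
#' noise-free ground truth (masks, boundary curves, key point,
#' thickness), then applies multiplicative speckle and Gaussian blur.
#' Fully deterministic: the same parameters (including seed) give a
#' bit-identical phantom.
#'
#' @param params a [phantom_params()] object.
#' @return A list of class `dcf_phantom` with elements `image` (a
#'   calibrated [gray_image()]) and `truth`: `dcf_mask`, `scm_mask`,
#'   `vertebra_masks` ([labeled_objects()], labels ordered left to
#'   right), `upper_curve`/`lower_curve` (outer DCF sheath boundaries),
#'   `key_point`, `thickness_cm`, `thickness_px`, `roi`, `scm_roi`,
#'   `spacing_cm` and the generating `params`.  All truth coordinates
#'   are in full-image frame.
#' @export
generate_phantom <- function(params = phantom_params()) {
  stopifnot(inherits(params, "phantom_params"))
  p <- params
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(p$seed)

  h <- p$height; w <- p$width
  rx0 <- p$roi[1L]; ry0 <- p$roi[2L]; rx1 <- p$roi[3L]; ry1 <- p$roi[4L]
  roi_w <- rx1 - rx0; roi_h <- ry1 - ry0

  thickness_cm <- p$thickness_cm %||%
    stats::runif(1L, p$thickness_range_cm[1L], p$thickness_range_cm[2L])
  t_px <- as.integer(round_half_up(thickness_cm / p$spacing_cm[["y"]]))
  if (t_px <= 2L * p$fascia_px)
    stop("phantom geometry cannot fit: DCF thickness does not exceed ",
         "twice the fascia thickness", call. = FALSE)

  vert_w <- p$vert_core_w + 2 * p$vert_margin_px
  vert_h <- p$vert_core_h + 2 * p$vert_margin_px
  first_left <- p$vert_first_left + if (p$shift_right) roi_w %/% 2L else 0L
  vert_top <- p$sheath_top_px + t_px + p$vert_offset_px
  if (ry0 + vert_top + vert_h > p$height)
    stop("phantom geometry cannot fit: vertebrae extend below the image",
         call. = FALSE)

  canvas <- matrix(p$i_background, h, w)

  # skin line
  canvas[(p$skin_rows[1L] + 1L):(p$skin_rows[2L] + 1L), ] <- p$i_skin

  # SCM sheath (image coordinates), mildly bowed
  scm_cols <- (rx0 + p$sheath_inset_px):(rx1 - 1L - p$sheath_inset_px)
  half <- (length(scm_cols) - 1) / 2
  bow <- round_half_up(p$scm_bow_px *
                         ((scm_cols - mean(scm_cols)) / half)^2)
  scm <- draw_sheath(canvas, scm_cols, p$scm_outer_top + bow,
                     p$scm_thickness_px, p$scm_fascia_px, p$cap_px,
                     p$i_fascia, p$i_scm)
  canvas <- scm$canvas

  # blood vessel between SCM and DCF
  vessel <- superellipse_mask(h, w, p$vessel_center[1L], p$vessel_center[2L],
                              p$vessel_axes[1L], p$vessel_axes[2L], p = 2)
  canvas[vessel] <- p$i_vessel

  # DCF sheath inside the ROI
  dcf_cols <- (rx0 + p$sheath_inset_px):(rx1 - 1L - p$sheath_inset_px)
  bow <- round_half_up(p$bow_px * ((dcf_cols - mean(dcf_cols)) / half)^2)
  y_up <- ry0 + p$sheath_top_px + bow
  dcf <- draw_sheath(canvas, dcf_cols, y_up, t_px, p$fascia_px, p$cap_px,
                     p$i_fascia, p$i_dcf)
  canvas <- dcf$canvas

  # vertebrae: dim halo, bright core, acoustic shadow below
  vert_label <- matrix(0L, h, w)
  for (k in seq_len(p$vert_count)) {
    left <- first_left + (k - 1L) * (vert_w + p$vert_gap_px)
    cx <- rx0 + left + (vert_w - 1) / 2
    cy <- ry0 + vert_top + (vert_h - 1) / 2
    halo <- superellipse_mask(h, w, cx, cy, vert_w / 2, vert_h / 2)
    if (!any(halo)) next
    core <- superellipse_mask(h, w, cx, cy, p$vert_core_w / 2,
                              p$vert_core_h / 2)
    sh_rows <- clamp(floor(cy + vert_h / 2) + seq_len(p$shadow_px), 0, h - 1)
    sh_cols <- clamp(round_half_up(cx + c(-1, 1) * vert_w / 2), 0, w - 1)
    canvas[(min(sh_rows) + 1L):(max(sh_rows) + 1L),
           (sh_cols[1L] + 1L):(sh_cols[2L] + 1L)] <- p$i_shadow
    canvas[halo] <- p$i_vert_margin
    canvas[core] <- p$i_vert_core
    vert_label[halo] <- k
  }

  truth <- list(
    dcf_mask = binary_image(dcf$mask),
    scm_mask = binary_image(scm$mask),
    vertebra_masks = labeled_objects(vert_label),
    upper_curve = boundary_curve(dcf_cols, dcf$y_upper),
    lower_curve = boundary_curve(dcf_cols, dcf$y_lower),
    thickness_cm = t_px * p$spacing_cm[["y"]],
    thickness_px = t_px,
    roi = p$roi, scm_roi = p$scm_roi,
    spacing_cm = p$spacing_cm, params = p)
  truth$key_point <- truth_key_point(vert_label)

  # speckle then blur, the standard B-mode texture approximation
  if (p$speckle_var > 0) {
    shape <- 1 / p$speckle_var
    canvas <- canvas * matrix(stats::rgamma(h * w, shape = shape,
                                            rate = shape), h, w)
    canvas <- clamp(canvas, 0, 255)
  }
  if (p$blur_sigma > 0)
    canvas <- .convolve_sep(canvas, gaussian_kernel(p$blur_sigma))
  img <- gray_image(clamp(round_half_up(canvas), 0, 255), p$spacing_cm)

  structure(list(image = img, truth = truth), class = "dcf_phantom")
}

# rightmost pixel of the leftmost vertebra blob, ties to the smaller y
truth_key_point <- function(vert_label) {
  objs <- labeled_objects(vert_label)
  if (n_objects(objs) == 0L) return(NULL)
  st <- objs$stats
  lead <- st$label[order(st$x_left, st$y_top)][1L]
  idx <- which(vert_label == lead)
  hh <- nrow(vert_label)
  x0 <- (idx - 1L) %/% hh; y0 <- (idx - 1L) %% hh
  xmax <- max(x0)
  c(x = xmax, y = min(y0[x0 == xmax]))
}

#' Generate a batch of phantoms
#'
#' Phantom `i` uses seed `base_seed + i - 1`; with `thickness_cm` unset
#' each phantom draws its own thickness from the configured range, so a
#' batch spans the study's thickness distribution.
#'
#' @param n number of phantoms (>= 1).
#' @param params template [phantom_params()]; the seed field is
#'   overridden per phantom.
#' @param base_seed seed of the first phantom.
#' @return A list of `dcf_phantom` objects.
#' @export
generate_batch <- function(n, params = phantom_params(), base_seed = 1L) {
  stopifnot(n >= 1L)
  lapply(seq_len(n), function(i) {
    params$seed <- as.integer(base_seed + i - 1L)
    generate_phantom(params)
  })
}

#' Write phantom ground truth to files
#'
#' Masks go to strictly binary PNGs (`<prefix>_dcf.png`,
#' `<prefix>_scm.png`, one `<prefix>_vert<k>.png` per vertebra); scalars
#' and boundary curves go to `<prefix>_truth.json`.  The round trip via
#' [read_truth()] is lossless.
#'
#' @param truth the `truth` element of a [generate_phantom()] result.
#' @param prefix output path prefix; the directory must exist.
#' @return The JSON path, invisibly.
#' @export
write_truth <- function(truth, prefix) {
  if (!dir.exists(dirname(prefix)))
    stop("cannot write truth: directory does not exist: '",
         dirname(prefix), "'", call. = FALSE)
  write_image(truth$dcf_mask, paste0(prefix, "_dcf.png"))
  write_image(truth$scm_mask, paste0(prefix, "_scm.png"))
  st <- truth$vertebra_masks$stats
  for (k in st$label)
    write_image(binary_image(truth$vertebra_masks$label_map == k),
                paste0(prefix, "_vert", k, ".png"))
  meta <- list(
    thickness_cm = truth$thickness_cm,
    thickness_px = truth$thickness_px,
    key_point = as.list(truth$key_point),
    roi = truth$roi, scm_roi = truth$scm_roi,
    spacing_cm = as.list(truth$spacing_cm),
    n_vertebrae = nrow(st),
    upper_curve = list(x = truth$upper_curve$x, y = truth$upper_curve$y),
    lower_curve = list(x = truth$lower_curve$x, y = truth$lower_curve$y))
  path <- paste0(prefix, "_truth.json")
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read phantom ground truth back from files
#'
#' @param prefix the prefix used by [write_truth()].
#' @return A truth list with the same masks, curves and scalars.
#' @export
read_truth <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_truth.json"),
                              simplifyVector = TRUE)
  dcf <- read_image(paste0(prefix, "_dcf.png"))
  scm <- read_image(paste0(prefix, "_scm.png"))
  lab <- matrix(0L, img_height(dcf), img_width(dcf))
  for (k in seq_len(meta$n_vertebrae)) {
    vm <- read_image(paste0(prefix, "_vert", k, ".png"))
    lab[vm$pixels == 255L] <- k
  }
  list(dcf_mask = binary_image(dcf$pixels),
       scm_mask = binary_image(scm$pixels),
       vertebra_masks = labeled_objects(lab),
       upper_curve = boundary_curve(meta$upper_curve$x, meta$upper_curve$y),
       lower_curve = boundary_curve(meta$lower_curve$x, meta$lower_curve$y),
       thickness_cm = meta$thickness_cm,
       thickness_px = meta$thickness_px,
       key_point = unlist(meta$key_point),
       roi = meta$roi, scm_roi = meta$scm_roi,
       spacing_cm = unlist(meta$spacing_cm))
}
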