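#' Pipeline configuration
#'
#' Collects every tunable constant of the extraction pipeline.  The
#' defaults are the published operating point: noise criteria 0.085 /
#' 0.1 / 0.5, membership cut 0.5, restoration divisor 1000, measuring
#' chords 1 cm either side of the key point.
#'
#' @param roi a [roi_spec()] or `c(x0, y0, x1, y1)`; `NULL` processes
#'   the full image.
#' @param alpha_cut fuzzy membership cut in `[0, 1]`.
#' @param noise_size_frac,left_margin_frac,min_width_frac noise-removal
#'   criteria constants (see [remove_noise_objects()]).
#' @param connectivity blob-labeling connectivity (default 8).
#' @param bridge_iterations gap-bridging passes after hole filling.
#' @param expand_radius dilation radius for the vertebra candidates.
#' @param fat_tolerance rows of slack when testing whether a candidate
#'   lies above the DCF lower boundary; defaults to
#'   `expand_radius + bridge_iterations + 1`, the systematic growth the
#'   earlier dilation steps introduce.
#' @param fat_min_below_frac fraction of an object's pixels that must
#'   reach below the DCF lower boundary for the object to count as a
#'   vertebra (default 0.05; see [remove_fat_false_positives()]).
#' @param restore_center Eq-style restoration center `c(x, y)` in ROI
#'   coordinates; `NULL` uses the ROI center.
#' @param restore_divisor divisor of the squared distance in the
#'   restoration weight (> 0).
#' @param pixel_spacing optional `c(x, y)` cm/px override used when the
#'   image carries no calibration.
#' @param side which side of the image the leftmost vertebra anatomy
#'   occupies; `"right"` mirrors every left/right convention.
#' @param measure_offset_px chord offset used only when no calibration
#'   is available at all (thickness then stays in pixels).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(roi = NULL, alpha_cut = 0.5,
                            noise_size_frac = 0.085,
                            left_margin_frac = 0.1,
                            min_width_frac = 0.5,
                            connectivity = 8L,
                            bridge_iterations = 1L,
                            expand_radius = 2L,
                            fat_tolerance = NULL,
                            fat_min_below_frac = 0.05,
                            restore_center = NULL,
                            restore_divisor = 1000,
                            pixel_spacing = NULL,
                            side = c("left", "right"),
                            measure_offset_px = 100L) {
  side <- match.arg(side)
  if (restore_divisor <= 0)
    stop("`restore_divisor` must be positive", call. = FALSE)
  if (!is.null(roi) && !inherits(roi, "roi_spec"))
    roi <- do.call(roi_spec, as.list(roi))
  structure(list(
    roi = roi, alpha_cut = alpha_cut,
    noise_size_frac = noise_size_frac,
    left_margin_frac = left_margin_frac,
    min_width_frac = min_width_frac,
    connectivity = as.integer(connectivity),
    bridge_iterations = as.integer(bridge_iterations),
    expand_radius = as.integer(expand_radius),
    fat_tolerance = fat_tolerance %||%
      (expand_radius + bridge_iterations + 1L),
    fat_min_below_frac = fat_min_below_frac,
    restore_center = restore_center,
    restore_divisor = restore_divisor,
    pixel_spacing = pixel_spacing,
    side = side,
    measure_offset_px = as.integer(measure_offset_px)),
    class = "pipeline_config")
}

stage_failure <- function(stage, reason) {
  structure(list(success = FALSE, failed_stage = stage, reason = reason),
            class = "stage_failure")
}

noise_filter <- function(objs, cfg, roi_w, roi_h) {
  remove_noise_objects(objs, roi_w, roi_h,
                       size_frac = cfg$noise_size_frac,
                       left_frac = cfg$left_margin_frac,
                       width_frac = cfg$min_width_frac,
                       side = cfg$side)
}

# per-column extreme rows of all traced contour points
contour_extremes <- function(contours) {
  pts <- do.call(rbind, unlist(contours, recursive = FALSE))
  agg_min <- tapply(pts[, "y"], pts[, "x"], min)
  agg_max <- tapply(pts[, "y"], pts[, "x"], max)
  xs <- as.integer(names(agg_min))
  list(upper = boundary_curve(xs, as.integer(agg_min)),
       lower = boundary_curve(xs, as.integer(agg_max)))
}

#' Extract the DCF candidate band from an ROI image
#'
#' Runs the candidate stage: ends-in stretch, average binarization,
#' blob labeling, size/location noise removal, per-column hole filling
#' between the detected upper and lower boundary objects, neighbor-gap
#' bridging, 4-directional contour tracing, and natural-spline
#' reconnection of the upper and lower boundary curves across any
#' columns the contour missed.
#'
#' @param roi_img the ROI-cropped [gray_image()].
#' @param cfg a [pipeline_config()].
#' @return On success, a list with `success = TRUE`, `dcf_mask` (filled
#'   candidate [binary_image()] in ROI frame), `dcf_upper`/`dcf_lower`
#'   ([boundary_curve()]s in ROI frame), `stretched` (the enhanced ROI,
#'   reused by the vertebra stage) and `stage_log` (object counts per
#'   stage).  When no object survives noise removal, a failure record
#'   with `success = FALSE` instead of an error.
#' @export
extract_dcf_candidate <- function(roi_img, cfg = pipeline_config()) {
  w <- img_width(roi_img); h <- img_height(roi_img)
  if (min(roi_img$pixels) == max(roi_img$pixels))
    return(stage_failure("extract_dcf_candidate", "constant (blank) ROI"))
  stretched <- ends_in_stretch(roi_img)
  bin <- average_binarize(stretched)
  objs <- blob_label(bin, cfg$connectivity)
  kept <- noise_filter(objs, cfg, w, h)
  log <- c(binarize = n_objects(objs), noise_removal = n_objects(kept))
  if (n_objects(kept) == 0L)
    return(stage_failure("extract_dcf_candidate",
                         "no object survives noise removal"))
  filled <- fill_between_boundaries(objects_to_mask(kept))
  bridged <- bridge_neighbor_gaps(filled, cfg$bridge_iterations)
  log <- c(log, bridged = n_objects(blob_label(bridged, cfg$connectivity)))
  contours <- contour_trace_4dir(bridged)
  ext <- contour_extremes(contours)
  dom <- range(ext$upper$x)
  list(success = TRUE,
       dcf_mask = bridged,
       dcf_upper = reconnect_boundary(ext$upper, dom, img_height = h),
       dcf_lower = reconnect_boundary(ext$lower, dom, img_height = h),
       stretched = stretched,
       stage_log = log)
}

#' Distance-weighted intensity restoration
#'
#' Multiplies every pixel by `1 + d^2 / divisor` where `d` is its
#' Euclidean distance from `center`, boosting intensities far from the
#' center (products are rounded half-up and clamped at 255).  Used when
#' the leftmost cervical vertebra was lost to thresholding: boosting the
#' image periphery lets a subsequent re-threshold recover it.
#'
#' @param img a [gray_image()].
#' @param center `c(x, y)` in the image's own (0-based) coordinates.
#' @param divisor positive scale of the squared distance (default 1000).
#' @return A [gray_image()].
#' @export
weighted_restore <- function(img, center, divisor = 1000) {
  if (divisor <= 0) stop("`divisor` must be positive", call. = FALSE)
  h <- img_height(img); w <- img_width(img)
  d2 <- outer((0:(h - 1) - center[[2L]])^2, (0:(w - 1) - center[[1L]])^2, `+`)
  alpha <- 1 + d2 / divisor
  gray_image(clamp(round_half_up(img$pixels * alpha), 0, 255),
             img$spacing_cm)
}

#' Remove fat false positives above the DCF lower boundary
#'
#' A bright object that does not reach below the DCF's lower boundary
#' cannot be a cervical vertebra (vertebrae lie beneath the muscle); it
#' is subcutaneous fat or fascia and is dropped.  A pixel `(x, y)` of an
#' object counts as "below" when `y >= boundary_y(x) + tolerance`
#' (columns outside the boundary's domain use the nearest covered
#' column); the object is removed iff its fraction of below pixels is
#' at most `min_below_frac`.  The defaults (`tolerance = 0`,
#' `min_below_frac = 0`) give the strict rule: removed iff entirely,
#' strictly above the boundary, so a straddling object is kept.  The
#' pipeline passes small positive values for both: the tolerance
#' absorbs the rows by which its earlier dilation steps systematically
#' deepened every object, and the fraction makes the decision robust to
#' stray speckle pixels fused to an object's underside.
#'
#' @param objs a [labeled_objects()].
#' @param dcf_lower a [boundary_curve()] in the same frame.
#' @param tolerance rows of slack (default 0).
#' @param min_below_frac fraction of an object's pixels that must reach
#'   below the boundary for it to count as a vertebra (default 0).
#' @return A [labeled_objects()] with the fat objects removed.
#' @export
remove_fat_false_positives <- function(objs, dcf_lower, tolerance = 0,
                                       min_below_frac = 0) {
  st <- objs$stats
  if (nrow(st) == 0L) return(objs)
  lm <- objs$label_map
  h <- nrow(lm)
  idx <- which(lm > 0L)
  lab <- lm[idx]
  x0 <- (idx - 1L) %/% h
  y0 <- (idx - 1L) %% h
  bx <- clamp(x0, min(dcf_lower$x), max(dcf_lower$x))
  by <- dcf_lower$y[match(bx, dcf_lower$x)]
  below <- y0 >= by + tolerance
  frac_below <- vapply(st$label, function(k) mean(below[lab == k]),
                       numeric(1L))
  drop <- frac_below <= min_below_frac
  if (any(drop)) lm[lm %in% st$label[drop]] <- 0L
  out <- labeled_objects(lm)
  attr(out, "n_removed") <- sum(drop)
  out
}

# one pass of the vertebra candidate chain on a binary image
vertebra_candidates <- function(bin, dcf_lower, cfg, roi_w, roi_h) {
  objs <- blob_label(bin, cfg$connectivity)
  kept <- noise_filter(objs, cfg, roi_w, roi_h)
  log <- c(labeled = n_objects(objs), noise_removal = n_objects(kept))
  if (n_objects(kept) == 0L)
    return(list(failure = TRUE, stage_log = log))
  expanded <- expand(objects_to_mask(kept), cfg$expand_radius)
  vobjs <- blob_label(expanded, cfg$connectivity)
  vobjs <- remove_fat_false_positives(vobjs, dcf_lower,
                                      tolerance = cfg$fat_tolerance,
                                      min_below_frac = cfg$fat_min_below_frac)
  log <- c(log, fat_removal = n_objects(vobjs))
  list(failure = n_objects(vobjs) == 0L, objects = vobjs, stage_log = log)
}

# is the anatomically leading vertebra on the wrong half of the ROI?
leading_misplaced <- function(objs, roi_w, side) {
  st <- objs$stats
  if (side == "left") min(st$x_left) >= roi_w / 2
  else max(st$x_right) < roi_w / 2
}

#' Extract cervical vertebra objects
#'
#' Vertebra stage: fuzzy sigma binarization of the enhanced ROI, blob
#' labeling, noise removal, expansion, and removal of fat false
#' positives above the DCF lower boundary.  If the surviving leading
#' vertebra sits on the wrong half of the ROI the true one was lost to
#' thresholding; the stage then applies [weighted_restore()] about the
#' ROI center and re-runs once with average binarization on the boosted
#' image before giving up.  Surviving objects are relabeled 1..k from
#' left to right and the vertebra upper boundary is assembled from the
#' per-column object tops, DDA-connected across the gaps between
#' neighboring vertebrae and spline-completed.
#'
#' @param roi_img the enhanced (stretched) ROI [gray_image()].
#' @param dcf_lower DCF lower [boundary_curve()] in ROI frame.
#' @param cfg a [pipeline_config()].
#' @return On success, a list with `success = TRUE`, `vertebrae`
#'   ([labeled_objects()] ordered left to right), `vert_upper`
#'   ([boundary_curve()]), `restored` (whether the weighted-restoration
#'   retry ran) and `stage_log`; otherwise a failure record.
#' @export
extract_vertebrae <- function(roi_img, dcf_lower, cfg = pipeline_config()) {
  w <- img_width(roi_img); h <- img_height(roi_img)
  fbin <- fuzzy_sigma_binarize(roi_img, cfg$alpha_cut)
  pass <- vertebra_candidates(fbin, dcf_lower, cfg, w, h)
  log <- c(fuzzy_binarize = 1L, pass$stage_log)
  restored <- FALSE
  if (pass$failure || leading_misplaced(pass$objects, w, cfg$side)) {
    restored <- TRUE
    center <- cfg$restore_center %||% c((w - 1) / 2, (h - 1) / 2)
    boosted <- weighted_restore(roi_img, center, cfg$restore_divisor)
    pass <- vertebra_candidates(average_binarize(boosted), dcf_lower,
                                cfg, w, h)
    log <- c(log, weighted_restore = 1L, pass$stage_log)
    if (pass$failure)
      return(c(stage_failure("extract_vertebrae",
                             "no vertebra candidate after restoration"),
               list(stage_log = log, restored = TRUE)))
    if (leading_misplaced(pass$objects, w, cfg$side))
      return(c(stage_failure("extract_vertebrae",
                             "leading vertebra on wrong half after restoration"),
               list(stage_log = log, restored = TRUE)))
  }
  vert <- order_left_to_right(pass$objects)
  list(success = TRUE, vertebrae = vert,
       vert_upper = vertebra_upper_boundary(vert, h),
       restored = restored, stage_log = log)
}

order_left_to_right <- function(objs) {
  st <- objs$stats
  ord <- st$label[order(st$x_left, st$y_top)]
  lm <- matrix(0L, nrow(objs$label_map), ncol(objs$label_map))
  for (i in seq_along(ord)) lm[objs$label_map == ord[i]] <- i
  labeled_objects(lm)
}

# per-column topmost vertebra rows, DDA-bridged between neighboring
# objects and spline-completed across any leftover gaps
vertebra_upper_boundary <- function(vert, img_height) {
  lm <- vert$label_map
  h <- nrow(lm)
  idx <- which(lm > 0L)
  x0 <- (idx - 1L) %/% h; y0 <- (idx - 1L) %% h
  top <- tapply(y0, x0, min)
  xs <- as.integer(names(top)); ys <- as.integer(top)
  pts <- data.frame(x = xs, y = ys)
  gaps <- which(diff(xs) > 1L)
  for (g in gaps) {
    seg <- dda_fill(c(xs[g], ys[g]), c(xs[g + 1L], ys[g + 1L]))
    seg <- seg[-c(1L, nrow(seg)), , drop = FALSE]
    pts <- rbind(pts, data.frame(x = seg[, "x"], y = seg[, "y"]))
  }
  pts <- pts[order(pts$x), ]
  curve <- boundary_curve(pts$x, pts$y)
  reconnect_boundary(curve, img_height = img_height)
}

#' Locate the thickness-measurement key point
#'
#' The key point is the rightmost pixel of the leftmost vertebra object
#' (smallest bounding-box `x_left`, ties to the smaller `y_top`); ties
#' on the rightmost column go to the smallest `y`.  For right-sided
#' anatomy the conventions mirror.
#'
#' @param vertebrae a [labeled_objects()] with at least one object.
#' @param side `"left"` (default) or `"right"`.
#' @return `c(x, y)` in the objects' frame.
#' @export
locate_key_point <- function(vertebrae, side = c("left", "right")) {
  side <- match.arg(side)
  st <- vertebrae$stats
  if (nrow(st) == 0L)
    stop("no vertebra objects to locate a key point in", call. = FALSE)
  lm <- vertebrae$label_map
  h <- nrow(lm)
  lead <- if (side == "left") st$label[order(st$x_left, st$y_top)][1L]
          else st$label[order(-st$x_right, st$y_top)][1L]
  idx <- which(lm == lead)
  x0 <- (idx - 1L) %/% h; y0 <- (idx - 1L) %% h
  xk <- if (side == "left") max(x0) else min(x0)
  c(x = xk, y = min(y0[x0 == xk]))
}

#' Measure DCF thickness on three vertical chords
#'
#' Vertical chords are taken at the key-point column and 1 cm to its
#' left and right (offset `round(1 / spacing_x)` pixels).  Each chord
#' runs from the DCF upper boundary to the lower boundary at that
#' column; its physical length is `(y_lower - y_upper) * spacing_y` and
#' the reported thickness is the arithmetic mean of the three chords.
#' Without any calibration the chords are measured in pixels at a
#' configurable offset and `thickness_cm` is `NA` (with a warning).
#'
#' @param dcf_upper,dcf_lower DCF boundary [boundary_curve()]s.
#' @param key_point `c(x, y)`.
#' @param spacing_cm `c(x, y)` cm/px, or `NULL` if unknown.
#' @param offset_px fallback chord offset when `spacing_cm` is `NULL`.
#' @return A list with `success`, `measure_xs`, `chords` (data frame
#'   `x`, `y_top`, `y_bottom`, `length_cm`, `length_px`),
#'   `thickness_cm`, `thickness_px`; or a failure record when a chord
#'   column falls outside a boundary's domain or the boundaries cross.
#' @export
measure_thickness <- function(dcf_upper, dcf_lower, key_point,
                              spacing_cm = NULL, offset_px = 100L) {
  if (is.null(spacing_cm)) {
    warning("no pixel spacing available: thickness reported in pixels; ",
            "supply `pixel_spacing` for centimetres")
    d <- as.integer(offset_px)
  } else {
    d <- as.integer(round_half_up(1 / spacing_cm[["x"]]))
  }
  xs <- key_point[["x"]] + c(-d, 0L, d)
  iu <- match(xs, dcf_upper$x); il <- match(xs, dcf_lower$x)
  if (anyNA(iu) || anyNA(il))
    return(stage_failure("measure_thickness",
                         "measuring column outside boundary domain"))
  y_top <- dcf_upper$y[iu]; y_bot <- dcf_lower$y[il]
  if (any(y_top >= y_bot))
    return(stage_failure("measure_thickness",
                         "upper boundary not above lower boundary"))
  len_px <- y_bot - y_top
  len_cm <- if (is.null(spacing_cm)) rep(NA_real_, 3L)
            else len_px * spacing_cm[["y"]]
  list(success = TRUE, measure_xs = xs,
       chords = data.frame(x = xs, y_top = y_top, y_bottom = y_bot,
                           length_cm = len_cm, length_px = len_px),
       thickness_cm = mean(len_cm), thickness_px = mean(len_px))
}

#' Run the full DCF extraction and thickness measurement pipeline
#'
#' Crops the ROI, extracts the DCF candidate band, extracts the
#' cervical vertebrae (with the conditional weighted-restoration
#' retry), locates the key point and measures the three-chord
#' thickness.  Deterministic: identical inputs and configuration give
#' bit-identical results.  Stage failures are reported in the result
#' (`success = FALSE`, `failed_stage`, `reason`), never thrown.
#'
#' @param image a [gray_image()].
#' @param cfg a [pipeline_config()].
#' @return An `ExtractionResult` of class `dcf_result`.  All
#'   coordinates (boundary curves, key point, chords) are in ROI frame;
#'   `roi` records the offset into the original image.
#' @export
run_pipeline <- function(image, cfg = pipeline_config()) {
  roi <- cfg$roi %||% roi_spec(0L, 0L, img_width(image), img_height(image))
  if (roi$x1 > img_width(image) || roi$y1 > img_height(image))
    return(finish_result(stage_failure("crop", "ROI exceeds image bounds"),
                         roi, cfg))
  roi_img <- crop_roi(image, roi)
  spacing <- if (!is.null(cfg$pixel_spacing)) {
    s <- cfg$pixel_spacing
    if (length(s) == 1L) s <- c(s, s)
    c(x = s[[1L]], y = s[[2L]])
  } else image$spacing_cm

  dcf <- extract_dcf_candidate(roi_img, cfg)
  if (!dcf$success) return(finish_result(dcf, roi, cfg))
  vert <- extract_vertebrae(dcf$stretched, dcf$dcf_lower, cfg)
  if (!vert$success)
    return(finish_result(vert, roi, cfg,
                         dcf_mask = dcf$dcf_mask, dcf_upper = dcf$dcf_upper,
                         dcf_lower = dcf$dcf_lower,
                         stage_log = c(dcf$stage_log, vert$stage_log)))
  key <- locate_key_point(vert$vertebrae, cfg$side)
  meas <- measure_thickness(dcf$dcf_upper, dcf$dcf_lower, key,
                            spacing_cm = spacing,
                            offset_px = cfg$measure_offset_px)
  log <- c(dcf$stage_log, vert$stage_log,
           vertebrae = n_objects(vert$vertebrae))
  base <- list(
    dcf_mask = dcf$dcf_mask, dcf_upper = dcf$dcf_upper,
    dcf_lower = dcf$dcf_lower, vertebrae = vert$vertebrae,
    vert_upper = vert$vert_upper, restored = vert$restored,
    key_point = key, spacing_cm = spacing, stage_log = log)
  if (!meas$success)
    return(finish_result(meas, roi, cfg, base))
  structure(c(list(success = TRUE, failed_stage = NA_character_,
                   reason = NA_character_, roi = roi, config = cfg),
              base,
              meas[c("measure_xs", "chords", "thickness_cm",
                     "thickness_px")]),
            class = "dcf_result")
}

finish_result <- function(failure, roi, cfg, extra = list(), ...) {
  extra <- c(extra, list(...))
  structure(c(list(success = FALSE, failed_stage = failure$failed_stage,
                   reason = failure$reason, roi = roi, config = cfg,
                   thickness_cm = NA_real_, thickness_px = NA_real_,
                   key_point = NULL),
              extra),
            class = "dcf_result")
}

#' @export
print.dcf_result <- function(x, ...) {
  if (x$success) {
    cat("<dcf_result> success\n")
    cat(sprintf("  key point: (%d, %d) [ROI frame]\n",
                x$key_point[["x"]], x$key_point[["y"]]))
    cat(sprintf("  chords (px): %s\n",
                paste(x$chords$length_px, collapse = ", ")))
    if (!is.na(x$thickness_cm))
      cat(sprintf("  thickness: %.4f cm\n", x$thickness_cm))
    else
      cat(sprintf("  thickness: %.1f px (uncalibrated)\n", x$thickness_px))
  } else {
    cat(sprintf("<dcf_result> FAILED at %s: %s\n",
                x$failed_stage, x$reason))
  }
  invisible(x)
}

#' Extract the sternocleidomastoid band
#'
#' The SCM sits above the blood vessel and, like the DCF, is a dark
#' band wrapped in bright fascia; the same candidate-extraction
#' operator applied to an upper-region ROI segments it.
#'
#' @param image a [gray_image()].
#' @param scm_roi ROI covering the SCM region.
#' @param cfg a [pipeline_config()].
#' @return As [extract_dcf_candidate()], in the SCM ROI frame.
#' @export
extract_scm <- function(image, scm_roi, cfg = pipeline_config()) {
  if (!inherits(scm_roi, "roi_spec"))
    scm_roi <- do.call(roi_spec, as.list(scm_roi))
  res <- extract_dcf_candidate(crop_roi(image, scm_roi), cfg)
  res$roi <- scm_roi
  res
}
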