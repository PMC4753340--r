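#' Labeled connected components
#'
#' Container pairing an integer label map (0 = background, `k >= 1` =
#' object id) with per-object geometry statistics.  Bounding-box
#' coordinates follow the package convention (0-based, x = column,
#' y = row).
#'
#' @param label_map integer matrix of labels.
#' @return An object of class `labeled_objects` with fields `label_map`
#'   and `stats`, a data frame with one row per object: `label`, `size`
#'   (pixel count), `x_left`, `y_top`, `x_right`, `y_bottom` (inclusive
#'   bounds), `width`, `height`.
#' @export
labeled_objects <- function(label_map) {
  storage.mode(label_map) <- "integer"
  h <- nrow(label_map)
  idx <- which(label_map > 0L)
  if (length(idx) == 0L) {
    stats <- data.frame(label = integer(), size = integer(),
                        x_left = integer(), y_top = integer(),
                        x_right = integer(), y_bottom = integer(),
                        width = integer(), height = integer())
  } else {
    lab <- label_map[idx]
    y0 <- (idx - 1L) %% h          # 0-based row
    x0 <- (idx - 1L) %/% h         # 0-based column
    labs <- sort(unique(lab))
    f <- factor(lab, levels = labs)
    stats <- data.frame(
      label    = labs,
      size     = as.integer(tabulate(f)),
      x_left   = as.integer(tapply(x0, f, min)),
      y_top    = as.integer(tapply(y0, f, min)),
      x_right  = as.integer(tapply(x0, f, max)),
      y_bottom = as.integer(tapply(y0, f, max)))
    stats$width  <- stats$x_right - stats$x_left + 1L
    stats$height <- stats$y_bottom - stats$y_top + 1L
    rownames(stats) <- NULL
  }
  structure(list(label_map = label_map, stats = stats),
            class = "labeled_objects")
}

#' @export
print.labeled_objects <- function(x, ...) {
  cat(sprintf("<labeled_objects> %d object(s) on a %d x %d grid\n",
              nrow(x$stats), ncol(x$label_map), nrow(x$label_map)))
  if (nrow(x$stats)) print(x$stats)
  invisible(x)
}

#' Number of objects
#' @param objs a [labeled_objects()].
#' @return Object count.
#' @export
n_objects <- function(objs) nrow(objs$stats)

#' Connected-component (blob) labeling
#'
#' Groups foreground pixels into maximal connected objects.  Labels are
#' assigned in raster-scan first-encounter order (top row first, then
#' left to right), starting at 1.
#'
#' @param bin a [binary_image()].
#' @param connectivity 4 or 8 (default 8, which keeps
#'   speckle-fragmented structures together).
#' @return A [labeled_objects()].
#' @export
blob_label <- function(bin, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L))
    stop("`connectivity` must be 4 or 8", call. = FALSE)
  labeled_objects(.cc_label(bin$pixels, as.integer(connectivity)))
}

#' Remove noise objects by size and location criteria
#'
#' An object `O` is removed iff
#' `S(O) < size_frac * S(ROI)` or
#' (`O.left < left_frac * W(ROI)` and `Width(O) < width_frac * W(ROI)`),
#' with `S(ROI) = roi_width * roi_height` and strict inequalities at all
#' three thresholds.  The size clause drops speckle fragments; the
#' location clause drops narrow objects hugging the left margin, where
#' no fascia or vertebral structure of interest starts.  For a
#' right-dominant anatomy (`side = "right"`) the location clause is
#' mirrored to the right margin.  Surviving objects keep their pixels
#' and labels.
#'
#' @param objs a [labeled_objects()].
#' @param roi_width,roi_height dimensions of the ROI the objects live in
#'   (defaults: the label-map dimensions).
#' @param size_frac,left_frac,width_frac the three criteria constants
#'   (defaults 0.085, 0.1, 0.5).
#' @param side `"left"` (default) or `"right"`; which margin the
#'   location clause guards.
#' @return A [labeled_objects()] containing only the survivors; the
#'   number of removed objects is attached as attribute `"n_removed"`.
#' @export
remove_noise_objects <- function(objs, roi_width = ncol(objs$label_map),
                                 roi_height = nrow(objs$label_map),
                                 size_frac = 0.085, left_frac = 0.1,
                                 width_frac = 0.5, side = c("left", "right")) {
  side <- match.arg(side)
  st <- objs$stats
  s_roi <- roi_width * roi_height
  # thresholds rounded to 12 significant digits so that e.g.
  # 0.085 * 10000 compares as exactly 850 (strict inequalities as
  # printed must not flip on binary representation error)
  small <- st$size < signif(size_frac * s_roi, 12)
  margin <- if (side == "left") st$x_left < signif(left_frac * roi_width, 12)
            else st$x_right > signif((1 - left_frac) * roi_width, 12) - 1
  skew <- margin & (st$width < signif(width_frac * roi_width, 12))
  drop <- small | skew
  lm <- objs$label_map
  if (any(drop)) lm[lm %in% st$label[drop]] <- 0L
  out <- labeled_objects(lm)
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Convert labeled objects back to a binary mask
#' @param objs a [labeled_objects()].
#' @return A [binary_image()] with the objects' pixels as foreground.
#' @export
objects_to_mask <- function(objs) binary_image(objs$label_map > 0L)

#' Fill holes between the upper and lower boundary per column
#'
#' For every column, all pixels between the first foreground row found
#' scanning down from the top and the first found scanning up from the
#' bottom are set to foreground.  Columns with no foreground are left
#' unchanged.  This closes the interior of a muscle band whose bright
#' fascia envelope was detected but whose body thresholded dark.
#' Idempotent.
#'
#' @param bin a [binary_image()].
#' @return A [binary_image()].
#' @export
fill_between_boundaries <- function(bin) {
  fg <- fg_mask(bin)
  filled <- apply(fg, 2L, function(col) {
    w <- which(col)
    if (length(w) >= 2L) col[w[1L]:w[length(w)]] <- TRUE
    col
  })
  binary_image(matrix(filled, nrow = nrow(fg)))
}

#' Bridge single-pixel gaps between neighboring foreground pixels
#'
#' Each iteration promotes to foreground every background pixel that is
#' 8-adjacent to a foreground pixel (one dilation step with a 3x3
#' structuring element), reconnecting boundary lines broken by the
#' earlier contrast operations.  Foreground never shrinks.
#'
#' @param bin a [binary_image()].
#' @param iterations number of passes (>= 1; default 1).
#' @return A [binary_image()].
#' @export
bridge_neighbor_gaps <- function(bin, iterations = 1L) {
  if (!is.numeric(iterations) || iterations < 1L)
    stop("`iterations` must be at least 1", call. = FALSE)
  p <- bin$pixels
  for (i in seq_len(iterations)) p <- .dilate_square(p, 1L) * 255L
  binary_image(p)
}

#' Morphological expansion (dilation)
#'
#' Dilation with a square structuring element of side
#' `2 * kernel_radius + 1`, used to restore small discontinuities in
#' the vertebra candidates.  Monotone: foreground only grows.
#'
#' @param bin a [binary_image()].
#' @param kernel_radius radius in pixels (>= 1).
#' @return A [binary_image()].
#' @export
expand <- function(bin, kernel_radius = 1L) {
  if (!is.numeric(kernel_radius) || kernel_radius < 1L)
    stop("`kernel_radius` must be at least 1", call. = FALSE)
  binary_image(.dilate_square(bin$pixels, as.integer(kernel_radius)) * 255L)
}

# Brute-force boundary set: foreground pixels with at least one
# background 4-neighbor or on the image border.
boundary_pixel_mask <- function(fg) {
  h <- nrow(fg); w <- ncol(fg)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- fg
  open4 <- !pad[1:h, 2:(w + 1L)] | !pad[3:(h + 2L), 2:(w + 1L)] |
           !pad[2:(h + 1L), 1:w] | !pad[2:(h + 1L), 3:(w + 2L)]
  fg & open4
}

# rotate a direction index (1=N, 2=E, 3=S, 4=W)
rot_left  <- function(d) ((d - 2L) %% 4L) + 1L
rot_right <- function(d) (d %% 4L) + 1L

# Square-tracing turtle: walk the foreground/background interface that
# passes through (r, c) heading `dir`, keeping background on the left.
# Returns the ordered fg pixels visited (rows of cbind(r, c), 1-based).
trace_loop <- function(fg, r, c, dir) {
  dr <- c(-1L, 0L, 1L, 0L); dc <- c(0L, 1L, 0L, -1L)
  h <- nrow(fg); w <- ncol(fg)
  start_r <- r; start_c <- c; start_dir <- dir
  rows <- integer(0); cols <- integer(0)
  limit <- 8L * (h * w) + 8L
  for (step in seq_len(limit)) {
    inside <- r >= 1L && r <= h && c >= 1L && c <= w && fg[r, c]
    if (inside) {
      rows <- c(rows, r); cols <- c(cols, c)
      dir <- rot_left(dir)
    } else {
      dir <- rot_right(dir)
    }
    r <- r + dr[dir]; c <- c + dc[dir]
    if (r == start_r && c == start_c && dir == start_dir) break
  }
  cbind(rows, cols)
}

#' 4-directional contour tracing
#'
#' Traces the boundary of every foreground object as an ordered, closed
#' walk restricted to the four axial directions, starting at the
#' object's top-leftmost pixel.  Objects are taken as 4-connected
#' components (the adjacency the 4-directional search defines).  An
#' object with interior holes yields one additional closed sequence per
#' hole boundary, so that together the sequences cover every boundary
#' pixel (a foreground pixel with a background 4-neighbor or on the
#' image border) at least once.
#'
#' @param bin a [binary_image()].
#' @return A list with one element per object (in raster order); each
#'   element is a list of integer matrices with columns `x`, `y`
#'   (0-based), the first being the outer contour.
#' @export
contour_trace_4dir <- function(bin) {
  fg <- fg_mask(bin)
  lab <- .cc_label(bin$pixels, 4L)
  nlab <- max(lab)
  if (nlab == 0L) return(list())
  bmask <- boundary_pixel_mask(fg)
  h <- nrow(fg)
  out <- vector("list", nlab)
  for (k in seq_len(nlab)) {
    obj <- lab == k
    visited <- matrix(FALSE, h, ncol(fg))
    loops <- list()
    todo <- which(obj & bmask)
    # raster (row-major) order among 0-based coords
    ord <- order((todo - 1L) %% h, (todo - 1L) %/% h)
    for (i in todo[ord]) {
      r <- ((i - 1L) %% h) + 1L
      c <- ((i - 1L) %/% h) + 1L
      if (visited[r, c]) next
      # direction whose left-hand side is a background 4-neighbor
      bg_dir <- bg_neighbor_dir(fg, r, c)
      loop <- trace_loop(fg, r, c, rot_right(bg_dir))
      visited[loop] <- TRUE
      # the walk may brush pixels whose only background contact is
      # diagonal; the contour proper keeps 4-boundary pixels only
      loop <- loop[bmask[loop], , drop = FALSE]
      # collapse consecutive duplicates, drop closing repeat of start
      if (nrow(loop) > 1L) {
        keep <- c(TRUE, rowSums(abs(diff(loop))) > 0L)
        loop <- loop[keep, , drop = FALSE]
        n <- nrow(loop)
        if (n > 1L && all(loop[n, ] == loop[1L, ]))
          loop <- loop[-n, , drop = FALSE]
      }
      loops[[length(loops) + 1L]] <-
        cbind(x = unname(loop[, 2L]) - 1L, y = unname(loop[, 1L]) - 1L)
    }
    out[[k]] <- loops
  }
  out
}

# first axial direction (1=N,2=E,3=S,4=W) pointing at a background
# pixel or the border from (r, c)
bg_neighbor_dir <- function(fg, r, c) {
  h <- nrow(fg); w <- ncol(fg)
  if (r == 1L || !fg[r - 1L, c]) return(1L)
  if (c == w  || !fg[r, c + 1L]) return(2L)
  if (r == h  || !fg[r + 1L, c]) return(3L)
  4L
}
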