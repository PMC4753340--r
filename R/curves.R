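#' Boundary curve
#'
#' An ordered polyline with at most one point per image column, used for
#' fascia and muscle boundaries: `x` strictly increasing, one `y` per
#' `x`.
#'
#' @param x,y integer pixel coordinates (0-based).
#' @return An object of class `boundary_curve`: a data frame with
#'   columns `x` and `y`.
#' @export
boundary_curve <- function(x, y) {
  if (length(x) != length(y))
    stop("`x` and `y` must have the same length", call. = FALSE)
  if (is.unsorted(x, strictly = TRUE))
    stop("`x` must be strictly increasing (one point per column)",
         call. = FALSE)
  structure(data.frame(x = as.numeric(x), y = as.numeric(y)),
            class = c("boundary_curve", "data.frame"))
}

#' Fit a natural cubic spline through boundary points
#'
#' Interpolating cubic spline with natural end conditions (zero second
#' derivative at both end knots), solved with the Thomas algorithm on
#' the tridiagonal system for the knot second derivatives.  Handles
#' non-uniform knot spacing.  Each segment `i` is
#' `S_i(x) = a_i + b_i (x - x_i) + c_i (x - x_i)^2 + d_i (x - x_i)^3`.
#' With only two knots the spline degenerates to the straight segment
#' between them.
#'
#' @param knots a [boundary_curve()] (or data frame with `x`, `y`) with
#'   at least 2 points and strictly increasing `x`.
#' @return An object of class `natural_spline` with fields `x`, `y`
#'   (knots) and per-segment coefficient vectors `a`, `b`, `c`, `d`.
#' @export
fit_natural_spline <- function(knots) {
  x <- as.numeric(knots$x); y <- as.numeric(knots$y)
  n <- length(x)
  if (n < 2L) stop("at least 2 knots are required", call. = FALSE)
  if (anyDuplicated(x)) stop("duplicate knot x values", call. = FALSE)
  if (is.unsorted(x, strictly = TRUE))
    stop("knot x values must be strictly increasing", call. = FALSE)
  h <- diff(x)
  m <- numeric(n)  # knot second derivatives; natural ends stay 0
  if (n > 2L) {
    k <- n - 2L
    diag_  <- 2 * (h[1:k] + h[2:(k + 1L)])
    lower  <- h[2:(k + 1L)][-k]                            # h_i, i=2..k
    upper  <- h[2:(k + 1L)][-k]
    rhs    <- 6 * ((y[3:n] - y[2:(n - 1L)]) / h[2:(k + 1L)] -
                   (y[2:(n - 1L)] - y[1:k]) / h[1:k])
    # Thomas forward sweep
    cp <- numeric(k); dp <- numeric(k)
    cp[1L] <- if (k > 1L) upper[1L] / diag_[1L] else 0
    dp[1L] <- rhs[1L] / diag_[1L]
    if (k > 1L) {
      for (i in 2:k) {
        denom <- diag_[i] - lower[i - 1L] * cp[i - 1L]
        if (i < k) cp[i] <- upper[i] / denom
        dp[i] <- (rhs[i] - lower[i - 1L] * dp[i - 1L]) / denom
      }
    }
    sol <- numeric(k)
    sol[k] <- dp[k]
    if (k > 1L) for (i in (k - 1L):1L) sol[i] <- dp[i] - cp[i] * sol[i + 1L]
    m[2:(n - 1L)] <- sol
  }
  i <- seq_len(n - 1L)
  a <- y[i]
  b <- (y[i + 1L] - y[i]) / h - h * (2 * m[i] + m[i + 1L]) / 6
  cc <- m[i] / 2
  d <- (m[i + 1L] - m[i]) / (6 * h)
  structure(list(x = x, y = y, a = a, b = b, c = cc, d = d),
            class = "natural_spline")
}

#' Evaluate a natural spline
#'
#' Piecewise cubic evaluation on the segment containing each query
#' point.  Queries that coincide with a knot return the stored knot
#' value exactly.  No extrapolation: querying outside
#' `[min(knots), max(knots)]` is an error.
#'
#' @param model a [fit_natural_spline()] model.
#' @param x numeric vector of query columns.
#' @return Interpolated `y` values.
#' @export
eval_spline <- function(model, x) {
  xs <- model$x
  if (any(x < xs[1L] | x > xs[length(xs)]))
    stop("spline evaluated outside its domain [", xs[1L], ", ",
         xs[length(xs)], "] (no extrapolation)", call. = FALSE)
  seg <- findInterval(x, xs, rightmost.closed = TRUE)
  dx <- x - xs[seg]
  out <- model$a[seg] + model$b[seg] * dx + model$c[seg] * dx^2 +
    model$d[seg] * dx^3
  at_knot <- match(x, xs)
  hit <- !is.na(at_knot)
  out[hit] <- model$y[at_knot[hit]]
  out
}

#' Reconnect a boundary curve across missing columns
#'
#' Fills every integer column of `domain` that the curve does not cover
#' with the natural-spline interpolant through the known points, rounded
#' half-up to a pixel row (and clamped to the image when `img_height`
#' is given).  Known points are preserved exactly.
#'
#' @param curve a [boundary_curve()] with at least 2 points.
#' @param domain integer range `c(x_first, x_last)` to cover; defaults
#'   to the curve's own extent.  Must lie within the known columns (the
#'   spline does not extrapolate).
#' @param img_height optional image height used to clamp filled rows to
#'   `[0, img_height - 1]`.
#' @return A [boundary_curve()] with one point per column of `domain`.
#' @export
reconnect_boundary <- function(curve, domain = NULL, img_height = NULL) {
  if (nrow(curve) < 2L)
    stop("at least 2 known columns are required to reconnect",
         call. = FALSE)
  if (is.null(domain)) domain <- range(curve$x)
  if (domain[1L] < min(curve$x) || domain[2L] > max(curve$x))
    stop("`domain` must lie within the known columns", call. = FALSE)
  xs <- seq(domain[1L], domain[2L])
  known <- match(xs, curve$x)
  y <- curve$y[known]
  gaps <- is.na(known)
  if (any(gaps)) {
    model <- fit_natural_spline(curve)
    filled <- round_half_up(eval_spline(model, xs[gaps]))
    if (!is.null(img_height)) filled <- clamp(filled, 0, img_height - 1)
    y[gaps] <- filled
  }
  boundary_curve(xs, y)
}

#' Rasterize a line segment with the DDA algorithm
#'
#' Digital Differential Analyzer: for each integer `x` from `x1` to
#' `x2` (inclusive) emits `(x, round(m * (x - x1) + y1))` with slope
#' `m = (y2 - y1) / (x2 - x1)` and half-up rounding, producing one pixel
#' per column with no column skipped.  A vertical segment (`x1 == x2`,
#' where the slope form is undefined) is handled by emitting every
#' integer `y` between the endpoints.
#'
#' @param p1,p2 numeric `c(x, y)` endpoints.
#' @return Integer matrix with columns `x`, `y`, ordered from `p1` to
#'   `p2`.
#' @export
dda_fill <- function(p1, p2) {
  x1 <- p1[[1L]]; y1 <- p1[[2L]]
  x2 <- p2[[1L]]; y2 <- p2[[2L]]
  if (x1 == x2) {
    ys <- if (y1 <= y2) seq(y1, y2) else seq(y1, y2, by = -1)
    return(cbind(x = as.integer(rep(x1, length(ys))), y = as.integer(ys)))
  }
  m <- (y2 - y1) / (x2 - x1)
  xs <- if (x1 <= x2) seq(x1, x2) else seq(x1, x2, by = -1)
  cbind(x = as.integer(xs),
        y = as.integer(round_half_up(m * (xs - x1) + y1)))
}
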