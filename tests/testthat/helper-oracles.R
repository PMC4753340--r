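# Independent oracles and fixture builders used across the suite.

rand_gray <- function(w, h) {
  gray_image(matrix(sample(0:255, w * h, replace = TRUE), h, w))
}

rand_binary <- function(w, h, p = 0.4) {
  binary_image(matrix(stats::runif(w * h) < p, h, w))
}

# Recursive/stack flood-fill connected-component labeling, raster-scan
# seed order.  Written independently of the package's C++ labeling.
flood_label <- function(fg, connectivity) {
  h <- nrow(fg); w <- ncol(fg)
  offs <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  if (connectivity == 8L)
    offs <- c(offs, list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
  lab <- matrix(0L, h, w)
  nxt <- 0L
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!fg[r, c] || lab[r, c] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(r, c))
    lab[r, c] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (o in offs) {
        rr <- p[1L] + o[1L]; cc <- p[2L] + o[2L]
        if (rr >= 1L && rr <= h && cc >= 1L && cc <= w &&
            fg[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- nxt
          stack[[length(stack) + 1L]] <- c(rr, cc)
        }
      }
    }
  }
  lab
}

# canonical relabeling by raster-order first encounter, for comparing
# partitions irrespective of label ids
canonical_labels <- function(lab) {
  h <- nrow(lab)
  idx <- which(t(lab) > 0L)  # raster order over the transposed matrix
  first <- t(lab)[idx]
  map <- integer(max(lab))
  nxt <- 0L
  for (l in first) if (map[l] == 0L) { nxt <- nxt + 1L; map[l] <- nxt }
  out <- lab
  out[lab > 0L] <- map[lab[lab > 0L]]
  out
}

# Dense-solve natural cubic spline: assembles the full tridiagonal
# system for the interior second derivatives and solves it with
# base solve(), independently of the package's Thomas sweep.
spline_oracle <- function(x, y) {
  n <- length(x); h <- diff(x)
  m <- rep(0, n)
  if (n > 2L) {
    k <- n - 2L
    A <- matrix(0, k, k); b <- numeric(k)
    for (i in seq_len(k)) {
      A[i, i] <- 2 * (h[i] + h[i + 1L])
      if (i > 1L) A[i, i - 1L] <- h[i]
      if (i < k) A[i, i + 1L] <- h[i + 1L]
      b[i] <- 6 * ((y[i + 2L] - y[i + 1L]) / h[i + 1L] -
                   (y[i + 1L] - y[i]) / h[i])
    }
    m[2:(n - 1L)] <- solve(A, b)
  }
  i <- seq_len(n - 1L)
  list(a = y[i],
       b = (y[i + 1L] - y[i]) / h - h * (2 * m[i] + m[i + 1L]) / 6,
       c = m[i] / 2,
       d = (m[i + 1L] - m[i]) / (6 * h),
       m = m)
}

rhu <- function(x) floor(x + 0.5)

# brute-force boundary pixel set: foreground with a background
# 4-neighbor or on the image border
brute_boundary <- function(fg) {
  h <- nrow(fg); w <- ncol(fg)
  out <- matrix(FALSE, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (!fg[r, c]) next
    if (r == 1L || r == h || c == 1L || c == w ||
        !fg[r - 1L, c] || !fg[r + 1L, c] || !fg[r, c - 1L] || !fg[r, c + 1L])
      out[r, c] <- TRUE
  }
  out
}
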