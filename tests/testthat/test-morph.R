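test_that("blob labeling honors connectivity semantics", {
  empty <- binary_image(matrix(FALSE, 5, 5))
  expect_equal(n_objects(blob_label(empty)), 0L)
  diag2 <- matrix(FALSE, 4, 4)
  diag2[2, 2] <- diag2[3, 3] <- TRUE
  expect_equal(n_objects(blob_label(binary_image(diag2), 4L)), 2L)
  expect_equal(n_objects(blob_label(binary_image(diag2), 8L)), 1L)
  expect_error(blob_label(empty, 6L), "connectivity")
})

test_that("blob labeling partitions agree with the flood-fill oracle", {
  set.seed(101)
  for (i in 1:100) {
    bin <- rand_binary(20, 20, p = stats::runif(1, 0.2, 0.6))
    fg <- bin$pixels == 255L
    for (conn in c(4L, 8L)) {
      got <- blob_label(bin, conn)$label_map
      want <- flood_label(fg, conn)
      expect_identical(canonical_labels(got), canonical_labels(want))
    }
  }
})

test_that("per-object statistics describe the labeled pixels", {
  m <- matrix(FALSE, 6, 8)
  m[2:4, 3:6] <- TRUE
  m[6, 1] <- TRUE
  st <- blob_label(binary_image(m))$stats
  expect_equal(nrow(st), 2L)
  big <- st[st$size == 12L, ]
  expect_equal(unlist(big[c("x_left", "y_top", "x_right", "y_bottom",
                            "width", "height")]),
               c(x_left = 2L, y_top = 1L, x_right = 5L, y_bottom = 3L,
                 width = 4L, height = 3L))
})

test_that("noise removal implements the printed size/location criteria", {
  # ROI 100 x 100: S(ROI) = 10000, size cut 850, left cut 10, width cut 50
  rect <- function(rows, cols) {
    mm <- matrix(FALSE, 100, 100)
    mm[rows, cols] <- TRUE
    blob_label(binary_image(mm))
  }
  # 849 pixels (< 850), central: removed by the size clause alone
  expect_equal(n_objects(remove_noise_objects(rect(31:47, 21:69 + 10))), 0L)
  expect_equal(17L * 49L, 833L)  # strictly below the cut
  # 850 pixels at the strict threshold: kept
  expect_equal(n_objects(remove_noise_objects(rect(31:40, 15:99))), 1L)
  expect_equal(10L * 85L, 850L)
  # left-skew clause: x_left 5 (< 10), width 40 (< 50), size 2000 -> removed
  expect_equal(n_objects(remove_noise_objects(rect(1:50, 6:45))), 0L)
  # same x_left but width 60 (>= 50), size 2040: kept
  expect_equal(n_objects(remove_noise_objects(rect(1:34, 6:65))), 1L)
  # right-sided convention mirrors the margin clause
  right_skew <- rect(1:50, 56:95)  # x_right = 94 > 0.9 * 100 - 1
  expect_equal(n_objects(remove_noise_objects(right_skew, side = "right")), 0L)
  expect_equal(n_objects(remove_noise_objects(right_skew, side = "left")), 1L)
})

test_that("noise removal decisions match the formula on all clause combinations", {
  # ROI 100 x 100; construct objects hitting every combination of
  # (small size, left start, narrow width)
  roi_w <- 100L; roi_h <- 100L
  cases <- expand.grid(small = c(TRUE, FALSE), left = c(TRUE, FALSE),
                       narrow = c(TRUE, FALSE))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    x_left <- if (cs$left) 5L else 20L
    width <- if (cs$narrow) 40L else 60L
    # choose a height giving size below or above 850 within the width
    height <- if (cs$small) max(1L, 800L %/% width) else (2400L %/% width) + 1L
    size <- height * width
    if (cs$small) expect_lt(size, 850L) else expect_gte(size, 850L)
    m <- matrix(FALSE, roi_h, roi_w)
    m[seq_len(height), x_left + seq_len(width)] <- TRUE
    objs <- blob_label(binary_image(m))
    kept <- remove_noise_objects(objs, roi_w, roi_h)
    should_remove <- (size < 0.085 * roi_w * roi_h) ||
      (x_left < 0.1 * roi_w && width < 0.5 * roi_w)
    expect_equal(n_objects(kept), as.integer(!should_remove),
                 info = paste(unlist(cs), collapse = "/"))
    # survivors keep their pixels untouched
    if (n_objects(kept) == 1L)
      expect_identical(kept$label_map, objs$label_map)
  }
})

test_that("hole filling spans each column between first and last foreground", {
  m <- matrix(FALSE, 12, 3)
  m[c(4, 10), 2] <- TRUE
  out <- fill_between_boundaries(binary_image(m))
  expect_identical(which(out$pixels[, 2] == 255L), 4:10)
  expect_true(all(out$pixels[, c(1, 3)] == 0L))
  solid <- binary_image(matrix(TRUE, 6, 2))
  expect_identical(fill_between_boundaries(solid)$pixels, solid$pixels)
  empty <- binary_image(matrix(FALSE, 4, 4))
  expect_identical(fill_between_boundaries(empty)$pixels, empty$pixels)
  # idempotence
  set.seed(31)
  bin <- rand_binary(15, 15)
  once <- fill_between_boundaries(bin)
  expect_identical(fill_between_boundaries(once)$pixels, once$pixels)
})

test_that("gap bridging dilates by one 8-neighborhood per iteration", {
  m <- matrix(FALSE, 7, 7); m[4, 4] <- TRUE
  out <- bridge_neighbor_gaps(binary_image(m))
  expect_identical(out$pixels == 255L,
                   unname(outer(1:7, 1:7, function(r, c)
                     abs(r - 4) <= 1 & abs(c - 4) <= 1)))
  # two pixels 2 apart on a row become one 4-connected component
  m2 <- matrix(FALSE, 5, 7); m2[3, c(2, 4)] <- TRUE
  out2 <- bridge_neighbor_gaps(binary_image(m2))
  expect_equal(n_objects(blob_label(out2, 4L)), 1L)
  full <- binary_image(matrix(TRUE, 4, 4))
  expect_identical(bridge_neighbor_gaps(full)$pixels, full$pixels)
  expect_error(bridge_neighbor_gaps(full, 0L), "at least 1")
})

test_that("expansion is a square dilation with composable radius", {
  m <- matrix(FALSE, 9, 9); m[5, 5] <- TRUE
  bin <- binary_image(m)
  expect_identical(expand(bin, 1L)$pixels,
                   bridge_neighbor_gaps(bin, 1L)$pixels)
  empty <- binary_image(matrix(FALSE, 5, 5))
  expect_identical(expand(empty, 2L)$pixels, empty$pixels)
  set.seed(41)
  for (i in 1:10) {
    bin <- rand_binary(16, 16, p = 0.15)
    expect_identical(expand(bin, 2L)$pixels,
                     expand(expand(bin, 1L), 1L)$pixels)
    expect_identical(expand(bin, 3L)$pixels,
                     expand(expand(bin, 1L), 2L)$pixels)
  }
})

test_that("contour tracing starts top-left, closes, and covers the boundary set", {
  single <- matrix(FALSE, 4, 4); single[2, 3] <- TRUE
  tr <- contour_trace_4dir(binary_image(single))
  expect_length(tr, 1L)
  expect_identical(tr[[1L]][[1L]], cbind(x = 2L, y = 1L))

  sq <- matrix(FALSE, 5, 5); sq[2:4, 2:4] <- TRUE
  loops <- contour_trace_4dir(binary_image(sq))[[1L]]
  expect_length(loops, 1L)
  pts <- loops[[1L]]
  expect_equal(nrow(pts), 8L)                      # center excluded
  expect_false(any(pts[, "x"] == 2L & pts[, "y"] == 2L))
  expect_identical(unname(pts[1L, ]), c(1L, 1L))   # top-leftmost start
  # closed: consecutive pixels (with wraparound) stay adjacent
  d <- abs(pts - pts[c(2:nrow(pts), 1L), ])
  expect_true(all(pmax(d[, 1L], d[, 2L]) <= 1L))

  set.seed(51)
  for (i in 1:30) {
    bin <- rand_binary(18, 18, p = stats::runif(1, 0.25, 0.7))
    fg <- bin$pixels == 255L
    traced <- contour_trace_4dir(bin)
    got <- do.call(rbind, unlist(traced, recursive = FALSE))
    got_set <- unique(paste(got[, "x"], got[, "y"]))
    want <- which(brute_boundary(fg), arr.ind = TRUE)
    want_set <- paste(want[, 2L] - 1L, want[, 1L] - 1L)
    expect_setequal(got_set, want_set)
  }
})
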