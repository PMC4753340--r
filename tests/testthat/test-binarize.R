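test_that("average binarization thresholds at the mean with >= tie rule", {
  img <- gray_image(matrix(c(0L, 0L, 255L, 255L), 2, 2))
  expect_identical(average_binarize(img)$pixels, img$pixels)
  # constant image: every pixel equals the mean, so all foreground
  expect_true(all(average_binarize(gray_image(matrix(9L, 3, 3)))$pixels ==
                    255L))
  img3 <- gray_image(matrix(c(10L, 20L, 30L), 1, 3))
  expect_identical(as.vector(average_binarize(img3)$pixels),
                   c(0L, 255L, 255L))
})

test_that("Otsu matches exhaustive between-class-variance search", {
  bimodal <- gray_image(matrix(rep(c(10L, 200L), each = 32L), 8, 8))
  out <- otsu_binarize(bimodal)
  expect_identical(out$pixels == 255L, bimodal$pixels == 200L)
  two <- gray_image(matrix(c(0L, 255L, 0L, 255L), 2, 2))
  expect_identical(otsu_binarize(two)$pixels, two$pixels)
  expect_error(otsu_binarize(gray_image(matrix(5L, 2, 2))), "constant")

  brute_otsu <- function(v) {
    n <- length(v)
    best <- -Inf; best_t <- 0L
    for (t in 0:255) {
      lo <- v[v <= t]; hi <- v[v > t]
      if (!length(lo) || !length(hi)) next
      s <- (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
      if (s > best) { best <- s; best_t <- t }
    }
    best_t
  }
  set.seed(77)
  for (i in 1:50) {
    img <- rand_gray(16, 16)
    expect_equal(attr(otsu_binarize(img), "threshold"),
                 brute_otsu(as.vector(img$pixels)))
  }
})

test_that("fuzzy parameter derivation matches the four-step hand traces", {
  p <- fuzzy_sigma_params(p_min = 50, p_max = 200)
  expect_equal(p$p_mid, 125)
  expect_equal(p$p_min_f, 75); expect_equal(p$p_max_f, 75)
  expect_equal(p$p_mid_f, 125)      # 125 <= 50 + 0.75 * 150
  expect_equal(p$beta, 75)          # p_mid_f > p_max_f, p_min_f <= p_mid_f
  expect_equal(p$p_min_new, 50); expect_equal(p$p_max_new, 200)

  q <- fuzzy_sigma_params(p_min = 0, p_max = 255)
  expect_equal(q$p_mid, 127.5)
  expect_equal(q$p_mid_f, 127.5)
  expect_equal(q$beta, 127.5)
  expect_equal(c(q$p_min_new, q$p_max_new), c(0, 255))

  r <- fuzzy_sigma_params(p_min = 200, p_max = 240)
  expect_equal(r$p_mid, 220)
  expect_equal(r$p_mid_f, 220)      # 220 <= 200 + 0.75 * 40 fails the bright test
  expect_equal(r$beta, 20)
  expect_equal(c(r$p_min_new, r$p_max_new), c(200, 240))

  # with p_mid defined as the min/max midpoint, the step-2 bright-image
  # compensation condition p_mid > p_min + 0.75 (p_max - p_min) reduces
  # to 0.5 > 0.75 and can never fire: p_mid_f always equals p_mid
  s <- fuzzy_sigma_params(p_min = 250, p_max = 252)
  expect_equal(s$p_mid_f, 251)
  s2 <- fuzzy_sigma_params(p_min = 0, p_max = 240)
  expect_equal(s2$p_mid_f, 120)
})

test_that("the verbatim nested half-width conditional equals min-selection", {
  set.seed(13)
  for (i in 1:200) {
    lohi <- sort(sample(0:255, 2L))
    p <- fuzzy_sigma_params(p_min = lohi[1L], p_max = lohi[2L])
    expected <- if (p$p_mid_f > p$p_max_f) min(p$p_mid_f, p$p_min_f)
                else min(p$p_mid_f, p$p_max_f)
    expect_equal(p$beta, expected)
  }
})

test_that("sigma membership has the documented breakpoints and shape", {
  p <- fuzzy_sigma_params(p_min = 50, p_max = 200)
  expect_equal(fuzzy_membership(p$p_min_new, p), 0)
  expect_equal(fuzzy_membership(p$p_mid, p), 1)
  expect_equal(fuzzy_membership(87.5, p), 0.5)  # (87.5 - 50) / (125 - 50)
  # monotone non-decreasing and bounded over random parameter sets
  set.seed(19)
  for (i in 1:50) {
    lohi <- sort(sample(0:255, 2L))
    q <- fuzzy_sigma_params(p_min = lohi[1L], p_max = lohi[2L])
    u <- fuzzy_membership(0:255, q)
    expect_true(all(u >= 0 & u <= 1))
    expect_true(all(diff(u) >= 0))
  }
  # beta = 0 degenerates to a step at p_mid
  z <- fuzzy_sigma_params(p_min = 100, p_max = 100)
  expect_equal(z$beta, 0)
  expect_equal(fuzzy_membership(c(99, 100, 101), z), c(0, 1, 1))
})

test_that("fuzzy sigma binarization cuts the membership at alpha", {
  img <- gray_image(matrix(c(50L, 200L, 100L, 80L), 2, 2))
  out <- fuzzy_sigma_binarize(img)          # u(100) = 2/3, u(80) = 0.4
  expect_identical(as.vector(out$pixels), c(0L, 255L, 255L, 0L))
  expect_true(all(fuzzy_sigma_binarize(img, alpha_cut = 0)$pixels == 255L))
  out1 <- fuzzy_sigma_binarize(img, alpha_cut = 1)
  expect_identical(out1$pixels == 255L, img$pixels >= 125)
  expect_error(fuzzy_sigma_binarize(img, alpha_cut = 1.5), "alpha_cut")
})

test_that("raising the alpha cut never grows the foreground", {
  set.seed(23)
  for (i in 1:20) {
    img <- rand_gray(12, 12)
    cuts <- sort(stats::runif(4))
    masks <- lapply(cuts, function(a)
      fuzzy_sigma_binarize(img, alpha_cut = a)$pixels == 255L)
    for (j in seq_len(3L))
      expect_true(all(masks[[j]] | !masks[[j + 1L]]))  # superset relation
  }
})
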