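test_that("gray_image enforces its invariants", {
  expect_error(gray_image(matrix(-1, 2, 2)), "0, 255")
  expect_error(gray_image(matrix(300, 2, 2)), "0, 255")
  expect_error(gray_image(matrix(1, 2, 2), spacing_cm = c(0, 0.1)),
               "strictly positive")
  img <- gray_image(matrix(0:254, 5, 51), spacing_cm = 0.02)
  expect_identical(img$spacing_cm, c(x = 0.02, y = 0.02))
  expect_equal(img_width(img), 51L)
  expect_equal(img_height(img), 5L)
})

test_that("binary_image accepts only 0/255 and logical input", {
  expect_error(binary_image(matrix(c(0, 1), 1, 2)), "only the values")
  b <- binary_image(matrix(c(TRUE, FALSE), 1, 2))
  expect_identical(as.vector(b$pixels), c(255L, 0L))
})

test_that("crop_roi follows the half-open 0-based convention", {
  m <- matrix(0L, 30, 40)
  m[21, 11] <- 77L  # pixel (x=10, y=20)
  img <- gray_image(m, spacing_cm = 0.01)
  out <- crop_roi(img, roi_spec(10, 20, 12, 22))
  expect_equal(dim(out$pixels), c(2L, 2L))
  expect_equal(out$pixels[1L, 1L], 77L)
  expect_identical(out$spacing_cm, img$spacing_cm)
  # full-image ROI is the identity
  expect_identical(crop_roi(img, c(0, 0, 40, 30))$pixels, img$pixels)
  # degenerate and out-of-bounds ROIs are errors
  expect_error(roi_spec(5, 0, 5, 10), "x0 < x1")
  expect_error(crop_roi(img, c(0, 0, 41, 30)), "bounds")
})

test_that("nested crops compose into a single crop with summed offsets", {
  set.seed(11)
  img <- rand_gray(40, 30)
  twice <- crop_roi(crop_roi(img, c(5, 3, 35, 28)), c(2, 4, 20, 22))
  once <- crop_roi(img, c(7, 7, 25, 25))
  expect_identical(twice$pixels, once$pixels)
})

test_that("PNG and TIFF round trips are lossless for 8-bit images", {
  set.seed(42)
  for (ext in c("png", "tiff")) {
    for (i in 1:5) {
      img <- rand_gray(32, 32)
      path <- withr::local_tempfile(fileext = paste0(".", ext))
      write_image(img, path)
      expect_identical(read_image(path)$pixels, img$pixels)
    }
  }
})

test_that("color input converts by BT.601 luma weights", {
  arr <- array(0, dim = c(4, 4, 3))
  arr[, , 1] <- 120 / 255; arr[, , 2] <- 60 / 255; arr[, , 3] <- 250 / 255
  path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(arr, path)
  expected <- as.integer(floor(0.299 * 120 + 0.587 * 60 + 0.114 * 250 + 0.5))
  expect_true(all(read_image(path)$pixels == expected))
  expect_error(read_image(""), "not found")
  expect_error(read_image(withr::local_tempfile(fileext = ".bmp")),
               "not found|unsupported")
})

test_that("a synthetic 8-bit DICOM round-trips with identical pixels", {
  set.seed(7)
  m <- matrix(sample(0:255, 24 * 16, TRUE), 16, 24)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_test_dicom(path, m)
  img <- read_dicom(path)
  expect_identical(img$pixels, matrix(as.integer(m), 16, 24))
  expect_null(img$spacing_cm)
})

test_that("DICOM PixelSpacing in mm becomes spacing_cm", {
  m <- matrix(5L, 4, 6)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_test_dicom(path, m, spacing_mm = c(0.1, 0.1))
  expect_equal(read_dicom(path)$spacing_cm, c(x = 0.01, y = 0.01))
})

test_that("16-bit DICOM data are min-max rescaled to [0, 255]", {
  vals <- matrix(c(0L, 512L, 1023L, 100L, 900L, 1023L), 2, 3)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_test_dicom(path, vals, bits = 16L)
  expected <- matrix(as.integer(floor(255 * vals / 1023 + 0.5)), 2, 3)
  expect_identical(read_dicom(path)$pixels, expected)
})

test_that("implicit-VR little endian DICOM is readable too", {
  set.seed(8)
  m <- matrix(sample(0:255, 12 * 10, TRUE), 10, 12)
  path <- withr::local_tempfile(fileext = ".dcm")
  write_test_dicom(path, m, explicit = FALSE, spacing_mm = c(0.2, 0.5))
  img <- read_dicom(path)
  expect_identical(img$pixels, matrix(as.integer(m), 10, 12))
  expect_equal(img$spacing_cm, c(x = 0.05, y = 0.02))
})

test_that("unsupported DICOM features raise named format errors", {
  m <- matrix(1L, 4, 4)
  p1 <- withr::local_tempfile(fileext = ".dcm")
  write_test_dicom(p1, m, n_frames = 3L)
  expect_error(read_dicom(p1), "multi-frame")
  p2 <- withr::local_tempfile(fileext = ".dcm")
  write_test_dicom(p2, m, samples = 3L)
  expect_error(read_dicom(p2), "color")
  expect_error(read_dicom("no/such/file.dcm"), "not found")
  p3 <- withr::local_tempfile(fileext = ".dcm")
  writeBin(as.raw(1:64), p3)
  expect_error(read_dicom(p3), "DICOM")
})

test_that("mirror_image reverses columns and is an involution", {
  set.seed(5)
  img <- rand_gray(9, 4)
  m <- mirror_image(img)
  expect_identical(m$pixels[, 1L], img$pixels[, 9L])
  expect_identical(mirror_image(m)$pixels, img$pixels)
})
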