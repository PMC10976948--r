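test_that("calibration follows the reflectance formula and its edge cases", {
  wl <- c(440, 500, 560)
  arr <- function(x) hypercube(array(x, c(4, 4, 3)), wl, "raw")
  dark <- hypercube(array(100, c(4, 4, 3)), wl, "dark")
  white <- hypercube(array(900, c(4, 4, 3)), wl, "white")
  expect_equal(unique(as.vector(calibrate(arr(100), dark, white)$values)), 0)
  expect_equal(unique(as.vector(calibrate(arr(900), dark, white)$values)), 100)
  expect_equal(unique(as.vector(calibrate(arr(500), dark, white)$values)), 50)
})

test_that("calibration flags degenerate pixels and rejects mismatched cubes", {
  wl <- c(440, 500)
  raw <- hypercube(array(5, c(2, 2, 2)), wl, "raw")
  dark <- hypercube(array(10, c(2, 2, 2)), wl, "dark")
  white_bad <- hypercube(array(10, c(2, 2, 2)), wl, "white")
  expect_warning(out <- calibrate(raw, dark, white_bad), "white <= dark")
  expect_true(all(is.na(out$values)))
  white_small <- hypercube(array(900, c(3, 2, 2)),
                           wl, "white")
  expect_error(calibrate(raw, dark, white_small), "dimension")
  dark2 <- hypercube(array(1, c(2, 2, 2)), c(441, 500), "dark")
  white2 <- hypercube(array(900, c(2, 2, 2)), wl, "white")
  expect_error(calibrate(raw, dark2, white2), "wavelength")
})

test_that("band lookup is nearest-wavelength with ties to the lower band", {
  arr <- array(rep(1:3, each = 4), c(2, 2, 3))
  cube <- hypercube(arr, c(438.1, 440.0, 441.9), "calibrated")
  expect_equal(unique(as.vector(select_band(cube, 440))), 2)
  cube2 <- hypercube(arr[, , 1:2], c(430, 450), "calibrated")
  expect_equal(unique(as.vector(select_band(cube2, 440))), 1)
  expect_warning(plane <- select_band(cube, 1000), "outside")
  expect_equal(unique(as.vector(plane)), 3)
})

test_that("Otsu matches the exhaustive 256-bin scan on varied images", {
  set.seed(42)
  imgs <- list(
    matrix(sample(c(10, 90), 400, replace = TRUE), 20),
    matrix(c(rnorm(300, 20, 2), rnorm(300, 80, 2)), 20),
    matrix(runif(400, 0, 1), 20),
    matrix(c(rnorm(200, 5, 1), rnorm(100, 50, 5), rnorm(100, 90, 2)), 20))
  for (img in imgs) {
    got <- otsu_threshold(img, seeds_are = "below")
    expect_equal(got$threshold, otsu_oracle(as.vector(img)))
  }
})

test_that("Otsu separates a bimodal mixture at a central threshold", {
  set.seed(7)
  img <- matrix(c(rnorm(500, 20, 2), rnorm(500, 80, 2)), 25)
  got <- otsu_threshold(img, seeds_are = "below")
  expect_gt(got$threshold, 40)
  expect_lt(got$threshold, 60)
  expect_true(all(img[got$mask] < 50) && all(img[!got$mask] > 50))
})

test_that("inverting an image flips the mask but keeps the pixel partition", {
  set.seed(8)
  img <- matrix(c(rnorm(200, 10), rnorm(200, 60)), 20)
  a <- otsu_threshold(img, seeds_are = "below")
  b <- otsu_threshold(-img, seeds_are = "above")
  expect_identical(a$mask, b$mask)
  expect_error(otsu_threshold(matrix(5, 4, 4)), "degenerate")
})

test_that("Otsu agrees with an independent image-analysis implementation", {
  skip_if_not_installed("EBImage")
  set.seed(9)
  img <- matrix(runif(1024), 32)
  got <- otsu_threshold(img, seeds_are = "below")$threshold
  ref <- EBImage::otsu(EBImage::Image(img), range = range(img), levels = 256)
  expect_equal(got, ref, tolerance = 0.01)
})

test_that("connected components honour 8-connectivity, min_area and raster order", {
  m <- matrix(0, 12, 12)
  m[2:6, 2:6] <- 1          # block A (topmost-leftmost first)
  m[8:12, 8:12] <- 1        # block B
  sm <- label_components(m, min_area = 4)
  expect_equal(sm$n_seeds, 2)
  expect_equal(sm$labels[2, 2], 1L)
  expect_equal(sm$labels[8, 8], 2L)
  m2 <- matrix(0, 6, 6); m2[1, 1] <- 1; m2[2, 2] <- 1   # diagonal touch
  expect_equal(label_components(m2, min_area = 1)$n_seeds, 1)
  m3 <- matrix(0, 6, 6); m3[1, 1:2] <- 1                # 2-px speck
  expect_equal(label_components(m3, min_area = 4)$n_seeds, 0)
  expect_equal(label_components(matrix(0, 5, 5), min_area = 1)$n_seeds, 0)
})

test_that("segmentation of a synthetic cube recovers the ground-truth regions", {
  spec <- noiseless_spec(n_bands = 30, class_sizes = c(2, 2, 2))
  cb <- generate_cube(spec, cube_layout(n_seeds = 6))
  cal <- calibrate(cb$raw, cb$dark, cb$white)
  seg <- segment_seeds(cal, ref_nm = 440, min_area = 10)
  expect_equal(seg$seeds$n_seeds, 6)
  expect_identical(seg$seeds$labels, cb$truth$seed_mask)
  expect_equal(seg$table$reflectance, cb$truth$planted, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("mean-spectra extraction averages exactly over region pixels", {
  wl <- c(440, 500)
  vals <- array(0, c(4, 4, 2))
  vals[1, 1, ] <- c(40, 10); vals[1, 2, ] <- c(60, 30)
  vals[4, 4, ] <- c(7, 9)
  cube <- hypercube(vals, wl, "calibrated")
  labs <- matrix(0L, 4, 4); labs[1, 1] <- 1L; labs[1, 2] <- 1L; labs[4, 4] <- 2L
  sm <- structure(list(labels = labs, n_seeds = 2L, min_area = 1),
                  class = "seed_mask")
  tab <- extract_mean_spectra(cube, sm)
  expect_equal(tab$reflectance[1, ], c(50, 20), ignore_attr = TRUE)
  expect_equal(tab$reflectance[2, ], c(7, 9), ignore_attr = TRUE)  # 1-px region
})

test_that("wavelength trimming keeps the closed interval and pairs values correctly", {
  X <- matrix(rep(1:5, each = 2), 2)
  tab <- spectra_table(X, c(400, 420, 981.9, 982, 1000))
  out <- trim_wavelengths(tab, 420, 982)
  expect_equal(out$wavelengths, c(420, 981.9, 982))
  expect_equal(out$reflectance[1, ], c(2, 3, 4), ignore_attr = TRUE)
  ident <- trim_wavelengths(tab, 400, 1000)
  expect_equal(ident$reflectance, tab$reflectance)
  expect_error(trim_wavelengths(tab, 2000, 3000), "lo < hi|no band")
  expect_error(trim_wavelengths(tab, 1500, 1600), "no band")
})

test_that("ENVI round trip preserves geometry, wavelengths and values", {
  spec <- small_spec(n_bands = 12)
  cb <- generate_cube(spec, cube_layout(n_seeds = 2, image_rows = 20,
                                        image_cols = 30, radius_r = 3,
                                        radius_c = 3))
  path <- tempfile()
  write_envi(cb$raw, path)
  back <- read_envi(path)
  expect_equal(dim(back$values), dim(cb$raw$values))
  expect_equal(back$wavelengths, cb$raw$wavelengths, tolerance = 1e-6)
  expect_equal(back$values, cb$raw$values, tolerance = 1e-6)  # float32 storage
})
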