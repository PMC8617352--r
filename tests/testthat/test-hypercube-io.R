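test_that("ENVI write/read round-trips data and wavelengths losslessly", {
  set.seed(5)
  cube <- new_hypercube(array(stats::runif(4 * 4 * 5, 0, 1000), c(4, 4, 5)),
                        c(950, 1000, 1050, 1100, 1150))
  path <- tempfile()
  write_envi(cube, path)
  back <- read_envi(path)
  expect_identical(back$data, cube$data)
  expect_identical(back$wavelengths, cube$wavelengths)
})

test_that("header/payload inconsistencies raise format errors", {
  set.seed(6)
  cube <- new_hypercube(array(stats::runif(4 * 4 * 5), c(4, 4, 5)),
                        seq(1000, 1200, by = 50))
  path <- tempfile()
  write_envi(cube, path)
  hdr <- readLines(paste0(path, ".hdr"))
  # header claims one band too many for the payload
  writeLines(sub("^bands = 5", "bands = 6", hdr), paste0(path, ".hdr"))
  expect_error(read_envi(path), "format error")
  # missing wavelength field is reported by name
  writeLines(hdr[!grepl("^wavelength =", hdr)], paste0(path, ".hdr"))
  expect_error(read_envi(path), "wavelength")
})

test_that("hypercube constructor enforces its invariants", {
  expect_error(new_hypercube(matrix(1, 2, 2), 1:2), "3-D")
  expect_error(new_hypercube(array(1, c(2, 2, 3)), c(1000, 1100)),
               "bands dimension")
  expect_error(new_hypercube(array(1, c(2, 2, 2)), c(1100, 1000)),
               "strictly increasing")
  expect_error(new_hypercube(array(-1, c(2, 2, 2)), c(1000, 1100)),
               "non-negative")
})

test_that("reflectance calibration is the referenced linear map", {
  wl <- c(1000, 1500, 2000)
  dark <- matrix(100, 3, 3)   # samples x bands
  white <- matrix(1100, 3, 3)
  mk <- function(val) new_hypercube(array(val, c(2, 3, 3)), wl)
  r_white <- calibrate_reflectance(mk(1100), dark, white)
  expect_true(all(r_white$data == 1))
  r_dark <- calibrate_reflectance(mk(100), dark, white)
  expect_true(all(r_dark$data == 1e-4))   # clip floor
  r_mid <- calibrate_reflectance(mk(600), dark, white)
  expect_true(all(abs(r_mid$data - 0.5) < 1e-12))
  expect_equal(r_mid$mode, "reflectance")
  # white <= dark at a band is reported with the band
  bad_white <- white; bad_white[, 2] <- 90
  expect_error(calibrate_reflectance(mk(600), dark, bad_white),
               "calibration error.*2")
})

test_that("frame stacks are averaged before calibration", {
  wl <- c(1000, 1100)
  dark <- array(0, c(4, 2, 2)); dark[1, , ] <- 40  # mean 10
  white <- array(1010, c(4, 2, 2))
  raw <- new_hypercube(array(510, c(2, 2, 2)), wl)
  r <- calibrate_reflectance(raw, dark, white)
  expect_true(all(abs(r$data - 0.5) < 1e-12))
})

test_that("segmentation finds the beans and matches ground truth", {
  sc <- noiseless_scene()
  refl <- calibrate_reflectance(sc$cube$raw, sc$cube$dark, sc$cube$white)
  mask <- segment_beans(refl)
  expect_equal(max(mask), 10)
  agreement <- mean((mask == sc$cube$mask)[sc$cube$mask > 0])
  expect_gte(agreement, 0.99)
  # label order is top-to-bottom then left-to-right
  cent <- sapply(1:10, function(k) c(mean(row(mask)[mask == k]),
                                     mean(col(mask)[mask == k])))
  expect_true(all(diff(cent[2, 1:5]) > 0))        # first row, left to right
  expect_true(all(cent[1, 6:10] > cent[1, 1:5]))  # second row below first
})

test_that("segmentation label count ignores global illumination scaling", {
  sc <- noiseless_scene()
  refl <- calibrate_reflectance(sc$cube$raw, sc$cube$dark, sc$cube$white)
  mask1 <- segment_beans(refl)
  scaled_raw <- new_hypercube(sc$cube$raw$data * 1.7,
                              sc$cube$raw$wavelengths)
  mask2 <- segment_beans(calibrate_reflectance(scaled_raw,
                                               sc$cube$dark * 1.7,
                                               sc$cube$white * 1.7))
  expect_equal(max(mask2), max(mask1))
})

test_that("a background-only scene yields an empty mask with a warning", {
  wl <- seq(1000, 2000, by = 100)
  cube <- new_hypercube(array(0.05, c(10, 10, 11)), wl, mode = "reflectance")
  expect_warning(mask <- segment_beans(cube), "empty scene")
  expect_true(all(mask == 0))
})

test_that("mean-spectrum extraction equals a brute-force double loop", {
  set.seed(9)
  wl <- seq(1000, 1500, by = 100)
  cube <- new_hypercube(array(stats::runif(6 * 5 * 6), c(6, 5, 6)), wl,
                        mode = "reflectance")
  mask <- matrix(sample(0:2, 30, replace = TRUE), 6, 5)
  s <- extract_mean_spectrum(cube, mask, 2)
  oracle <- numeric(6)
  count <- 0
  for (l in 1:6) for (p in 1:5) if (mask[l, p] == 2) {
    oracle <- oracle + cube$data[l, p, ]
    count <- count + 1
  }
  expect_equal(s$values, oracle / count)
  expect_equal(s$mode, "reflectance")
  expect_error(extract_mean_spectrum(cube, mask, 9), "lookup error")
})

test_that("side averaging is element-wise and validates alignment", {
  wl <- c(1000, 1100)
  a <- new_spectrum(wl, c(0.2, 0.2), "reflectance")
  b <- new_spectrum(wl, c(0.6, 0.2), "reflectance")
  avg <- average_sides(a, b)
  expect_equal(avg$values, c(0.4, 0.2))
  expect_identical(average_sides(a, a)$values, a$values)
  expect_error(average_sides(a, new_spectrum(c(1000, 1200), c(0.6, 0.2),
                                             "reflectance")),
               "alignment error")
  expect_error(average_sides(a, new_spectrum(wl, c(0.1, 0.2), "absorbance")),
               "alignment error")
})

test_that("segment-extract-average reproduces generator spectra end to end", {
  # noiseless run through the full imaging chain, both sides
  cfg <- sim_config(n_batches = 1, beans_per_batch = 10, seed = 31)
  st <- simulate_study(cfg)
  recovered <- lapply(1:2, function(side) {
    hc <- generate_hypercube(st$spectra[[side]], st$wavelengths,
                             layout = c(2, 5), pixel_jitter = 0,
                             frame_noise_sd = 0)
    refl <- calibrate_reflectance(hc$raw, hc$dark, hc$white)
    mask <- segment_beans(refl)
    t(sapply(1:10, function(i) extract_mean_spectrum(refl, mask, i)$values))
  })
  for (side in 1:2)
    expect_lt(max(abs(recovered[[side]] - st$spectra[[side]])), 1e-6)
  avg <- average_sides(
    new_spectrum(st$wavelengths, recovered[[1]][1, ], "reflectance"),
    new_spectrum(st$wavelengths, recovered[[2]][1, ], "reflectance"))
  truth <- (st$spectra[[1]][1, ] + st$spectra[[2]][1, ]) / 2
  expect_lt(max(abs(avg$values - truth)), 1e-6)
})
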