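# IO conventions: lossless round trips, axis arithmetic, ROI geometry

test_that("integer images round-trip bit-exactly; colour input is rejected", {
  d <- withr::local_tempdir()
  m <- matrix(sample(0:65535, 64 * 64, replace = TRUE), 64, 64)
  img <- intensity_image(m, pixel_size_um = 0.5, channel_label = "SHG")
  p <- file.path(d, "u16.tif")
  write_image(img, p)
  back <- read_image(p)
  expect_identical(back$pixels, m * 1.0)
  expect_equal(back$pixel_size_um, 0.5)
  expect_equal(back$channel_label, "SHG")

  m8 <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
  p8 <- file.path(d, "u8.tif")
  write_image(intensity_image(m8, 1), p8)
  expect_identical(read_image(p8, 1)$pixels, m8 * 1.0)

  rgb <- array(runif(8 * 8 * 3), c(8, 8, 3))
  prgb <- file.path(d, "rgb.tif")
  tiff::writeTIFF(rgb, prgb)
  expect_error(read_image(prgb, 1), "single-channel")

  expect_error(intensity_image(m, pixel_size_um = 0), "positive")
  expect_error(intensity_image(matrix(0, 4, 4), 1), "at least 8 x 8")
})

test_that("float images (including negative noise excursions) round-trip", {
  d <- withr::local_tempdir()
  set.seed(1)
  m <- matrix(rnorm(64 * 64, mean = 30, sd = 12), 64, 64)  # has negatives
  p <- file.path(d, "f32.tif")
  write_image(intensity_image(m, 0.25, "SRS"), p)
  back <- read_image(p)
  expect_lt(max(abs(back$pixels - m)) / max(abs(m)), 1e-6)
  expect_equal(back$pixel_size_um, 0.25)
})

test_that("cube round trips preserve data and axis; page count is checked", {
  d <- withr::local_tempdir()
  ax <- ch_axis()
  expect_identical(n_channels(ax), 51L)  # floor((3075-2825)/5)+1
  set.seed(2)
  arr <- array(rnorm(16 * 16 * 51, 1, 0.3), c(16, 16, 51))
  cube <- hyperspectral_cube(arr, ax, 0.5)
  p <- file.path(d, "cube.tif")
  write_cube(cube, p)
  back <- read_cube(p)
  expect_lt(max(abs(back$data - arr)), 1e-6)
  expect_equal(back$axis, ax)
  expect_equal(back$pixel_size_um, 0.5)

  # axis -> sidecar -> axis is idempotent
  meta <- jsonlite::read_json(file.path(d, "cube.json"), simplifyVector = TRUE)
  ax2 <- wavenumber_axis(meta$start_cm1, meta$stop_cm1, meta$step_cm1)
  expect_identical(axis_values(ax2), axis_values(ax))

  # 50 pages against a 51-channel axis is rejected with both counts
  pages <- lapply(1:50, function(k) matrix(runif(64), 8, 8))
  p2 <- file.path(d, "short.tif")
  tiff::writeTIFF(pages, p2, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(start_cm1 = 2825, stop_cm1 = 3075, step_cm1 = 5,
                            pixel_size_um = 0.5),
                       file.path(d, "short.json"), auto_unbox = TRUE)
  expect_error(read_cube(p2), "50.*51")
})

test_that("wavenumber axis arithmetic and validation", {
  cases <- list(list(2825, 3075, 5, 51L), list(1600, 1800, 2, 101L),
                list(1000, 1001, 0.3, 4L))
  for (cs in cases)
    expect_identical(n_channels(wavenumber_axis(cs[[1]], cs[[2]], cs[[3]])),
                     cs[[4]])
  v <- axis_values(wavenumber_axis(2825, 3075, 5))
  expect_true(all(diff(v) > 0))
  expect_equal(v[1], 2825)
  expect_equal(v[51], 3075)
  expect_error(wavenumber_axis(3075, 2825, 5), "below")
  expect_error(wavenumber_axis(2825, 3075, 0), "positive")
})

test_that("ROI resolution matches brute-force pixel-centre enumeration", {
  shape <- c(32L, 32L)
  brute_disk <- function(center, r) {
    out <- NULL
    for (i in 1:32) for (j in 1:32)
      if ((i - center[1])^2 + (j - center[2])^2 <= r^2 + 1e-12)
        out <- rbind(out, c(i, j))
    out
  }
  for (cs in list(list(c(10, 10), 0.6), list(c(10, 10), 1), list(c(16, 16), 3.7),
                  list(c(5, 28), 2))) {
    got <- roi_pixels(roi_disk(cs[[1]], cs[[2]]), shape)
    want <- brute_disk(cs[[1]], cs[[2]])
    expect_equal(unname(got[order(got[, 1], got[, 2]), , drop = FALSE]),
                 want[order(want[, 1], want[, 2]), , drop = FALSE])
  }
  # r = 0.6 keeps only the centre pixel (4-neighbours are at distance 1)
  expect_equal(nrow(roi_pixels(roi_disk(c(10, 10), 0.6), shape)), 1L)

  mask <- matrix(TRUE, 32, 32)
  expect_equal(nrow(roi_pixels(roi_mask(mask), shape)), 32L * 32L)

  expect_error(roi_pixels(roi_polygon(rbind(c(-5, 1), c(40, 1), c(20, 50))),
                          shape), "bounds")
  expect_error(roi_pixels(roi_disk(c(10.5, 10.5), 0.2), shape), "empty")
})

test_that("spectra round-trip through the CSV dialect", {
  d <- withr::local_tempdir()
  sp <- spectrum(seq(1600, 1800, 2), runif(101), "test")
  p <- file.path(d, "sp.csv")
  write_spectrum(sp, p)
  expect_identical(readLines(p, n = 1L), "wavenumber_cm1,intensity")
  back <- read_spectrum(p)
  expect_equal(back$wavenumbers_cm1, sp$wavenumbers_cm1)
  expect_equal(back$intensities, sp$intensities)
  expect_error(spectrum(c(1, 1, 2), c(0, 0, 0)), "ascending")
  expect_error(spectrum(1:3, 1:2), "equal length")
})
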