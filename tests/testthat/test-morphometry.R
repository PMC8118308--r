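# segmentation and morphometry: Otsu, watershed, overlap rejection, length

test_that("Otsu threshold maximizes between-class variance (brute force)", {
  # perfectly bimodal image: threshold falls strictly between the two levels
  m <- matrix(10, 20, 20)
  m[sample(400, 40)] <- 100
  ot <- otsu_threshold(m)
  expect_gt(ot$threshold, 10); expect_lt(ot$threshold, 100)
  expect_identical(sum(ot$mask), sum(m == 100))

  # exhaustive oracle: scan every bin edge of the 256-bin histogram and
  # compute class weights and means directly from the bin counts
  brute_otsu <- function(m, n_bins = 256L) {
    lo <- min(m); hi <- max(m)
    bin <- pmin(floor((m - lo) / (hi - lo) * n_bins) + 1L, n_bins)
    counts <- tabulate(bin, n_bins)
    best <- -Inf; best_k <- NA
    for (k in seq_len(n_bins - 1L)) {
      n0 <- sum(counts[1:k]); n1 <- sum(counts) - n0
      if (n0 == 0 || n1 == 0) next
      mu0 <- sum(counts[1:k] * (1:k)) / n0
      mu1 <- sum(counts[(k + 1):n_bins] * ((k + 1):n_bins)) / n1
      v <- (n0 / sum(counts)) * (n1 / sum(counts)) * (mu0 - mu1)^2
      if (v > best + 1e-12) { best <- v; best_k <- k }
    }
    lo + best_k * (hi - lo) / n_bins
  }
  set.seed(10)
  for (k in 1:20) {
    m <- matrix(c(rnorm(240, 20, 6), rnorm(160, 70, 12)), 20, 20)
    expect_equal(otsu_threshold(m)$threshold, brute_otsu(m))
  }

  # inverting intensities selects the complement class
  m <- matrix(c(rnorm(300, 20, 4), rnorm(100, 80, 6)), 20, 20)
  ot1 <- otsu_threshold(m)
  ot2 <- otsu_threshold(max(m) - m)
  expect_identical(sum(ot1$mask) + sum(ot2$mask), length(m))

  expect_error(otsu_threshold(matrix(5, 10, 10)), "degenerate histogram")
})

test_that("watershed partitions foreground and splits dumbbells", {
  # two disjoint needles stay two labels equal to the connected components
  f <- small_field(n = 2L, seed = 11L)
  mask <- f$image$pixels > 35
  lab <- watershed_split(mask)
  expect_identical(max(lab), 2L)
  expect_true(all(lab[mask] > 0L))           # label partition
  expect_true(all(lab[!mask] == 0L))

  # dumbbell: two 9-px-wide blobs joined by a 2-px bridge -> 2 labels
  db <- matrix(FALSE, 40, 60)
  db[16:24, 10:18] <- TRUE
  db[16:24, 35:43] <- TRUE
  db[19:20, 19:34] <- TRUE
  lab <- watershed_split(db)
  expect_identical(max(lab), 2L)
  expect_true(lab[20, 14] != lab[20, 39])    # blob centres in different labels
  expect_true(all(lab[db] > 0L))

  # one convex blob is not over-split at the default marker depth
  blob <- matrix(FALSE, 40, 40)
  blob[10:30, 12:28] <- TRUE
  expect_identical(max(watershed_split(blob)), 1L)

  expect_warning(lab0 <- watershed_split(matrix(FALSE, 16, 16)), "empty")
  expect_true(all(lab0 == 0L))
})

test_that("length is the maximum Feret diameter in micrometres", {
  seg <- cbind(row = rep(5L, 41), col = 1:41)
  ml <- measure_length(seg, 0.5)
  expect_equal(ml$length_um, 20.5)

  single <- cbind(10L, 10L)
  expect_equal(measure_length(single, 0.7)$length_um, 0.7)
  expect_equal(measure_length(single, 0.7)$orientation_deg, 0)

  # brute-force oracle on random blobs; rotation by 90 degrees preserves the
  # length and shifts the orientation by 90 mod 180
  set.seed(20)
  for (k in 1:10) {
    px <- unique(cbind(sample(5:60, 30, TRUE), sample(5:60, 30, TRUE)))
    ml <- measure_length(px, 1)
    expect_equal(ml$length_um, feret_px_oracle(px))
    rot <- cbind(px[, 2], 70 - px[, 1])  # 90-degree rotation
    ml_r <- measure_length(rot, 1)
    expect_equal(ml_r$length_um, ml$length_um)
    expect_equal((ml_r$orientation_deg - ml$orientation_deg) %% 180, 90,
                 tolerance = 1e-6)
  }
})

test_that("overlap rejection passes isolated needles and fails crossings", {
  # two disjoint needles: both passed
  f2 <- small_field(n = 2L, seed = 11L, shape = c(96L, 96L))
  lab <- watershed_split(f2$image$pixels > 35)
  rej <- reject_overlaps(lab, 0.5)
  expect_identical(rej$objects$status, c("PASSED", "PASSED"))
  expect_true(all(rej$objects$overlap_fraction == 0))

  # single needle: passed
  f1 <- small_field(n = 1L, seed = 2L, shape = c(96L, 96L))
  rej1 <- reject_overlaps(watershed_split(f1$image$pixels > 35), 0.5)
  expect_identical(rej1$objects$status, "PASSED")

  # a midpoint crossing forms one connected component that watershed cannot
  # divide; the composite is detected by rectangle fill and split into two
  # needle parts, both failed as overlapping, with near-true lengths
  fx <- small_field(n = 0L, crossings = 1L, seed = 13L, shape = c(128L, 128L))
  labx <- watershed_split(fx$image$pixels > 35)
  expect_identical(max(labx), 1L)
  rejx <- reject_overlaps(labx, 0.5)
  expect_identical(nrow(rejx$objects), 2L)
  expect_true(all(rejx$objects$status == "FAILED_OVERLAP"))
  expect_true(all(abs(rejx$objects$length_um - 10) < 1.5))

  # undersized specks fail on size
  lab_s <- matrix(0L, 16, 16); lab_s[3, 3:5] <- 1L
  rej_s <- reject_overlaps(lab_s, 0.5)
  expect_identical(rej_s$objects$status, "FAILED_SIZE")
})

test_that("raising the overlap threshold never decreases the passed count", {
  f <- small_field(n = 14L, crossings = 2L, seed = 21L, shape = c(256L, 256L))
  lab <- watershed_split(f$image$pixels > 35)
  passed <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8), function(om) {
    rej <- reject_overlaps(lab, 0.5, morphometry_config(overlap_fraction_max = om))
    sum(rej$objects$status == "PASSED")
  }, numeric(1))
  expect_true(all(diff(passed) >= 0))
})

test_that("the composed pipeline recovers counts, density and lengths", {
  f <- small_field(n = 10L, seed = 31L, shape = c(256L, 256L), length_um = 12)
  mr <- run_morphometry(f$image)
  expect_identical(mr$n_passed, 10L)
  expect_equal(mr$density_per_mm2 * mr$analysis_area_mm2, mr$n_passed)
  expect_equal(mr$analysis_area_mm2, 256^2 * 0.25 / 1e6)

  m <- match_objects(mr, f$truth)
  expect_identical(nrow(m), 10L)
  expect_true(all(abs(m$est_length_um - m$true_length_um) <= 2 * 0.5))

  # a supplied plaque mask changes the density denominator
  pm <- matrix(FALSE, 256, 256); pm[1:128, ] <- TRUE
  mr_pm <- run_morphometry(f$image, plaque_mask = pm)
  expect_equal(mr_pm$analysis_area_mm2, mr$analysis_area_mm2 / 2)

  # background-only frame: nothing segmented
  empty <- intensity_image(matrix(10, 64, 64), 0.5)
  mr0 <- run_morphometry(empty)
  expect_identical(mr0$n_passed, 0L)
  expect_identical(mr0$density_per_mm2, 0)
})
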