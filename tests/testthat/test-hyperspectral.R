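# ROI spectra, spline representation, NNLS unmixing, band flags, calls

test_that("ROI spectra are per-channel means over the ROI pixels", {
  ax <- ch_axis()
  cls <- matrix("PROTEIN", 16, 16)
  cls[1:8, ] <- "CE_CRYSTAL_LINOLEATE"
  cube <- generate_cube(spectral_scene(cls, noise_sd = 0), ax)$cube
  lin <- synth_reference_spectrum("CHOLESTERYL_LINOLEATE", ax)$intensities
  prot <- synth_reference_spectrum("PROTEIN", ax)$intensities

  one <- extract_roi_spectrum(cube, roi_disk(c(4, 4), 0.4))
  expect_equal(one$intensities, lin)

  # constant-class region at zero noise: the reference exactly
  reg <- extract_roi_spectrum(cube, roi_disk(c(4, 8), 2.5))
  expect_equal(reg$intensities, lin)

  # two pixels from different classes: arithmetic mean
  mask <- matrix(FALSE, 16, 16); mask[4, 4] <- TRUE; mask[12, 4] <- TRUE
  two <- extract_roi_spectrum(cube, roi_mask(mask))
  expect_equal(two$intensities, (lin + prot) / 2)
})

test_that("spline smoothing is exact at knots and finds band centres", {
  w <- seq(2825, 3075, 5)
  y <- exp(-(w - 2958)^2 / (2 * 11^2))
  sp <- spectrum(w, y)
  sm <- smooth_spectrum(sp, 1)
  at_knots <- sm$intensities[match(w, sm$wavenumbers_cm1)]
  expect_lt(max(abs(at_knots - y)), 1e-9)

  # degree <= 3 polynomials are reproduced everywhere
  for (coef in list(c(2, 0.5, 0, 0), c(1, -2, 0.03, 0), c(0, 1, -0.01, 1e-4))) {
    x <- (w - 2950) / 50
    yp <- coef[1] + coef[2] * x + coef[3] * x^2 + coef[4] * x^3
    smp <- smooth_spectrum(spectrum(w, yp), 1)
    xs <- (smp$wavenumbers_cm1 - 2950) / 50
    expect_lt(max(abs(smp$intensities -
      (coef[1] + coef[2] * xs + coef[3] * xs^2 + coef[4] * xs^3))), 1e-8)
  }

  # Gaussian sampled at 5 cm-1, splined to 1 cm-1: argmax within 2 cm-1
  for (ctr in c(2931, 2958.5, 3007)) {
    yg <- exp(-(w - ctr)^2 / (2 * 10^2))
    smg <- smooth_spectrum(spectrum(w, yg), 1)
    expect_lt(abs(smg$wavenumbers_cm1[which.max(smg$intensities)] - ctr), 2)
  }

  expect_error(smooth_spectrum(sp, 5), "finer")
})

test_that("noiseless conic combinations are recovered exactly", {
  ax <- ch_axis()
  lib <- reference_library(ax)
  set.seed(30)
  for (k in 1:25) {
    ij <- sample(4, 2)
    wgt <- runif(1, 0.05, 0.95)
    y <- wgt * lib$entries[[ij[1]]]$intensities +
      (1 - wgt) * lib$entries[[ij[2]]]$intensities
    dec <- decompose_spectrum(spectrum(axis_values(ax), y), lib)
    truefr <- numeric(4); truefr[ij] <- c(wgt, 1 - wgt)
    expect_lt(max(abs(dec$fractions - truefr)), 1e-6)
    expect_lt(dec$residual_rms, 1e-9)
  }
  # pure basis element
  pure <- decompose_spectrum(lib$entries$CHOLESTEROL_MONOHYDRATE, lib)
  expect_gt(pure$fractions["CHOLESTEROL_MONOHYDRATE"], 0.99)
})

test_that("NNLS agrees with an exhaustive simplex grid search (2 members)", {
  ax <- ch_axis()
  lib2 <- reference_library(ax, species = c("CHOLESTEROL_MONOHYDRATE", "PROTEIN"))
  A1 <- lib2$entries[[1]]$intensities
  A2 <- lib2$entries[[2]]$intensities
  set.seed(31)
  for (k in 1:5) {
    wgt <- runif(1, 0.2, 0.8)
    y0 <- wgt * A1 + (1 - wgt) * A2
    y <- y0 + rnorm(length(y0), 0, 0.02)
    dec <- decompose_spectrum(spectrum(axis_values(ax), y), lib2)
    # oracle: scan the mixing fraction at step 0.01; scale and offset fitted
    # in closed form for each candidate
    yn <- y / max(y)
    best <- NULL
    for (cfr in seq(0, 1, 0.01)) {
      base <- cfr * A1 + (1 - cfr) * A2
      fit <- stats::lm.fit(cbind(base, 1), yn)
      rss <- sum(fit$residuals^2)
      if (is.null(best) || rss < best$rss) best <- list(rss = rss, c = cfr)
    }
    expect_lt(abs(dec$fractions[1] - best$c), 0.011)
  }
})

test_that("decomposition and calls are invariant to intensity scaling", {
  ax <- ch_axis()
  lib <- reference_library(ax)
  set.seed(32)
  s <- noisy_reference("CHOLESTERYL_LINOLEATE", ax, snr = 20)
  for (scale in c(0.03, 1, 250)) {
    sc <- spectrum(s$wavenumbers_cm1, s$intensities * scale)
    cc <- classify_composition(sc, lib)
    ref <- classify_composition(s, lib)
    expect_equal(cc$fractions, ref$fractions, tolerance = 1e-9)
    expect_identical(cc$dominant_class, ref$dominant_class)
    expect_identical(cc$unsaturation_band_present, ref$unsaturation_band_present)
  }
})

test_that("band detection flags real bands and ignores noise and shoulders", {
  ax <- ch_axis()
  unsat <- band_window(3010, 20, 0.05)
  set.seed(33)
  for (k in 1:15) {
    expect_true(detect_band(noisy_reference("CHOLESTERYL_LINOLEATE", ax), unsat)$present)
    expect_false(detect_band(noisy_reference("PROTEIN", ax), unsat)$present)
    expect_false(detect_band(noisy_reference("CHOLESTEROL_MONOHYDRATE", ax), unsat)$present)
  }
  # noiseless oleate still shows its (weaker) unsaturation band
  ole <- synth_reference_spectrum("CHOLESTERYL_OLEATE", ax)
  expect_true(detect_band(ole, unsat)$present)

  # a monotone spectrum has no interior peak anywhere
  mono <- spectrum(seq(2825, 3075, 5), seq(1, 0.1, length.out = 51))
  expect_false(detect_band(mono, band_window(2950, 20))$present)

  expect_error(detect_band(ole, band_window(1740, 20)), "outside")
})

test_that("composition calls follow the dominance rules on both axes", {
  want_class <- c(CHOLESTEROL_MONOHYDRATE = "FREE_CHOLESTEROL",
                  CHOLESTERYL_OLEATE = "CE_DOMINANT",
                  CHOLESTERYL_LINOLEATE = "CE_DOMINANT",
                  PROTEIN = "PROTEIN")
  for (axis in list(ch_axis(), fp_axis())) {
    lib <- reference_library(axis)
    set.seed(34)
    for (k in 1:10) for (sp in all_species) {
      cc <- classify_composition(noisy_reference(sp, axis), lib)
      expect_identical(cc$dominant_class, unname(want_class[sp]))
    }
  }
  # pooled esters dominate a 50/50 CE mixture
  ax <- ch_axis(); lib <- reference_library(ax)
  mix <- 0.5 * lib$entries$CHOLESTERYL_OLEATE$intensities +
    0.5 * lib$entries$CHOLESTERYL_LINOLEATE$intensities
  cc <- classify_composition(spectrum(axis_values(ax), mix), lib)
  expect_identical(cc$dominant_class, "CE_DOMINANT")

  # ester flag: NA off the fingerprint axis, set on it
  expect_true(is.na(cc$ester_band_present))
  lib_fp <- reference_library(fp_axis())
  cc_fp <- classify_composition(
    synth_reference_spectrum("CHOLESTERYL_OLEATE", fp_axis()), lib_fp)
  expect_true(cc_fp$ester_band_present)
  expect_true(is.na(cc_fp$unsaturation_band_present))

  # an axis covering neither diagnostic region is rejected
  expect_error(classify_composition(
    spectrum(seq(2000, 2200, 5), runif(41) + 0.5, "x"),
    reference_library(ch_axis())), "neither")
})
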