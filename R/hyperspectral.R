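# ROI spectra from hyperspectral cubes, spline representation, non-negative
# least-squares decomposition against the reference library, diagnostic band
# detection (3010 cm-1 unsaturation, 1740 cm-1 ester carbonyl) and the
# composition call.

#' Reference spectral library
#'
#' Peak-normalized reference spectra of the four species the crystal
#' composition is compared against: cholesterol monohydrate, cholesteryl
#' oleate, cholesteryl linoleate and protein, all on one common axis.
#'
#' @param axis a [wavenumber_axis].
#' @param band_table band table as from [default_band_table()].
#' @param species character vector of species to include.
#' @return object of class `reference_library` (named list of [spectrum]
#'   plus the axis).
#' @export
reference_library <- function(axis, band_table = default_band_table(),
                              species = REFERENCE_SPECIES) {
  entries <- lapply(stats::setNames(species, species),
                    synth_reference_spectrum, axis = axis,
                    band_table = band_table)
  structure(list(entries = entries, axis = axis), class = "reference_library")
}

#' @export
print.reference_library <- function(x, ...) {
  cat(fmt("<reference_library> %d species on %g-%g cm-1: %s\n",
          length(x$entries), x$axis$start_cm1, x$axis$stop_cm1,
          paste(names(x$entries), collapse = ", ")))
  invisible(x)
}

#' Read a reference library from a directory of CSV spectra
#'
#' One `<SPECIES>.csv` per species in the dialect of [write_spectrum()];
#' spectra must share one wavenumber axis and are peak-normalized on read.
#'
#' @param dir directory containing the CSV files.
#' @return a `reference_library`.
#' @export
read_reference_library <- function(dir) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  stop_if(length(files) == 0L, fmt("no CSV spectra found in %s", dir))
  entries <- lapply(files, read_spectrum)
  names(entries) <- toupper(vapply(files, function(f)
    tools::file_path_sans_ext(basename(f)), character(1)))
  w <- entries[[1L]]$wavenumbers_cm1
  for (e in entries)
    stop_if(!isTRUE(all.equal(e$wavenumbers_cm1, w)),
            "library spectra must share one wavenumber axis")
  entries <- lapply(entries, function(e)
    spectrum(e$wavenumbers_cm1, e$intensities / max(e$intensities), e$label))
  step <- min(diff(w))
  structure(list(entries = entries,
                 axis = wavenumber_axis(min(w), max(w) + step / 2, step)),
            class = "reference_library")
}

#' Extract the mean spectrum over a region of interest
#'
#' @param cube a [hyperspectral_cube].
#' @param roi an ROI (see [roi_pixels()]) valid for the cube's spatial shape.
#' @param label label for the returned spectrum.
#' @return a [spectrum]: per-channel mean intensity over the ROI pixels.
#' @export
extract_roi_spectrum <- function(cube, roi, label = "roi") {
  stop_if(!inherits(cube, "hyperspectral_cube"), "cube must be a hyperspectral_cube")
  px <- roi_pixels(roi, dim(cube$data)[1:2])
  flat <- matrix(cube$data, prod(dim(cube$data)[1:2]), dim(cube$data)[3L])
  idx <- px[, 1L] + (px[, 2L] - 1L) * dim(cube$data)[1L]
  y <- colMeans(flat[idx, , drop = FALSE])
  spectrum(axis_values(cube$axis), y, label)
}

#' Smooth a spectrum by cubic-spline interpolation onto a finer axis
#'
#' Interpolation is exact at the original sample points and reproduces
#' polynomials up to degree 3 (Forsythe-Malcolm-Moler end conditions); the
#' coarse 5 cm-1 sampling of the acquisition is represented as a smooth
#' trace for display and band detection.
#'
#' @param sp a [spectrum] with at least 4 points.
#' @param resample_step_cm1 target step, must be finer than the original.
#' @return a [spectrum] on the finer axis.
#' @export
smooth_spectrum <- function(sp, resample_step_cm1 = 1) {
  stop_if(!inherits(sp, "spectrum"), "sp must be a spectrum")
  stop_if(length(sp$intensities) < 4L, "need at least 4 spectral points")
  orig_step <- min(diff(sp$wavenumbers_cm1))
  stop_if(resample_step_cm1 >= orig_step,
          fmt("resample step (%g) must be finer than the original step (%g)",
              resample_step_cm1, orig_step))
  f <- stats::splinefun(sp$wavenumbers_cm1, sp$intensities, method = "fmm")
  w <- seq(min(sp$wavenumbers_cm1), max(sp$wavenumbers_cm1),
           by = resample_step_cm1)
  spectrum(w, f(w), sp$label)
}

# resample a spectrum onto arbitrary wavenumbers (spline through samples)
resample_onto <- function(sp, wavenumbers) {
  stop_if(min(wavenumbers) < min(sp$wavenumbers_cm1) - 1e-9 ||
            max(wavenumbers) > max(sp$wavenumbers_cm1) + 1e-9,
          "spectrum does not cover the target axis")
  f <- stats::splinefun(sp$wavenumbers_cm1, sp$intensities, method = "fmm")
  spectrum(wavenumbers, f(wavenumbers), sp$label)
}

#' Decompose a spectrum as a non-negative combination of library references
#'
#' Non-negative least squares: the spectrum is fitted as a conic combination
#' of the peak-normalized library entries plus a free constant baseline
#' (implemented as a +/- intercept pair inside the NNLS), which makes the
#' fractions invariant to additive offsets such as the residual left by
#' subtracting a noisy spectrum minimum. Coefficients are normalized to
#' fractions summing to 1; the residual RMS is reported in units of the
#' peak-normalized spectrum.
#'
#' @param sp a [spectrum]; resampled onto the library axis if it covers it.
#' @param library a [reference_library].
#' @param normalize peak-normalize the spectrum before fitting (default
#'   TRUE), making the decomposition scale invariant.
#' @param fit_offset include the free constant baseline (default TRUE).
#' @return list: `coefficients`, `fractions` (both named by species),
#'   `offset` and `residual_rms`.
#' @export
decompose_spectrum <- function(sp, library, normalize = TRUE,
                               fit_offset = TRUE) {
  stop_if(!inherits(library, "reference_library"),
          "library must be a reference_library")
  w <- library$entries[[1L]]$wavenumbers_cm1
  if (!isTRUE(all.equal(sp$wavenumbers_cm1, w))) sp <- resample_onto(sp, w)
  y <- sp$intensities
  if (normalize) {
    stop_if(max(y) <= 0, "spectrum has no positive intensity")
    y <- y / max(y)
  }
  A <- vapply(library$entries, function(e) e$intensities, numeric(length(w)))
  ns <- ncol(A)
  Afit <- if (fit_offset) cbind(A, 1, -1) else A
  fit <- pracma::lsqnonneg(Afit, y)
  coef <- stats::setNames(pmax(fit$x[seq_len(ns)], 0), names(library$entries))
  offset <- if (fit_offset) fit$x[ns + 1L] - fit$x[ns + 2L] else 0
  total <- sum(coef)
  fractions <- if (total > 0) coef / total else coef
  resid <- y - as.vector(A %*% coef) - offset
  list(coefficients = coef, fractions = fractions, offset = offset,
       residual_rms = sqrt(mean(resid^2)))
}

#' Diagnostic band window
#'
#' @param center_cm1 window centre in cm-1.
#' @param half_width_cm1 half width in cm-1 (default 20).
#' @param min_prominence minimum topographic prominence as a fraction of the
#'   spectrum maximum for the band to count as present (default 0.05).
#' @param noise_k multiple of the estimated noise level the matched-filter
#'   band amplitude must exceed (default 4.5); guards the prominence test
#'   against noise-induced spurious peaks.
#' @param template_fwhm_cm1 FWHM of the Gaussian band template used by the
#'   matched-filter gate; default 1.25 times the window half width.
#' @export
band_window <- function(center_cm1, half_width_cm1 = 20, min_prominence = 0.05,
                        noise_k = 4.5,
                        template_fwhm_cm1 = 1.25 * half_width_cm1) {
  structure(list(center_cm1 = center_cm1, half_width_cm1 = half_width_cm1,
                 min_prominence = min_prominence, noise_k = noise_k,
                 template_fwhm_cm1 = template_fwhm_cm1),
            class = "band_window")
}

# noise level of a sampled spectrum: MAD of the Savitzky-Golay residual,
# rescaled by the filter's exact white-noise residual norm
estimate_noise_sd <- function(y, p = 2L, n = 7L) {
  n <- min(n, length(y) - (1L - length(y) %% 2L))
  if (n < p + 2L) return(0)
  ys <- signal::sgolayfilt(y, p = p, n = n)
  h <- signal::sgolay(p = p, n = n)[(n + 1L) %/% 2L, ]
  delta <- rep(0, n); delta[(n + 1L) %/% 2L] <- 1
  core <- n:(length(y) - n + 1L)
  if (length(core) < 4L) core <- seq_along(y)
  stats::mad((y - ys)[core], center = 0) / sqrt(sum((delta - h)^2))
}

#' Detect a vibrational band inside a window
#'
#' Finds the strongest interior local maximum of the denoised
#' (Savitzky-Golay filtered, spline-resampled) spectrum inside the window;
#' the band is present when (a) the peak's topographic prominence reaches
#' `min_prominence` times the spectrum maximum and (b) the amplitude of a
#' Gaussian band template fitted at the window centre (jointly with a local
#' linear baseline) exceeds `noise_k` times its propagated uncertainty,
#' where the noise level is estimated from the spectrum's high-frequency
#' residual. Window endpoints and monotonic shoulders do not count as
#' peaks, and noise fluctuations alone do not trigger the flag.
#'
#' @param sp a [spectrum].
#' @param window a [band_window] lying inside the spectrum axis.
#' @return list: `present`, `peak_cm1` (NA when no peak), `prominence`,
#'   `band_amplitude`, `noise_sd`.
#' @export
detect_band <- function(sp, window) {
  stop_if(!inherits(window, "band_window"), "window must be a band_window")
  lo <- window$center_cm1 - window$half_width_cm1
  hi <- window$center_cm1 + window$half_width_cm1
  stop_if(lo < min(sp$wavenumbers_cm1) || hi > max(sp$wavenumbers_cm1),
          fmt("band window %g-%g cm-1 lies outside the spectrum axis", lo, hi))
  w0 <- sp$wavenumbers_cm1; y0 <- sp$intensities
  sig <- estimate_noise_sd(y0)
  n_sg <- min(7L, length(y0) - (1L - length(y0) %% 2L))
  ys <- if (n_sg >= 5L) signal::sgolayfilt(y0, p = 2, n = n_sg) else y0
  f <- stats::splinefun(w0, ys, method = "fmm")
  step <- min(1, min(diff(w0)))
  w <- seq(min(w0), max(w0), by = step)
  y <- f(w)
  n <- length(y)
  spec_max <- max(y)
  is_max <- c(FALSE, diff(y[-n]) > 0 & diff(y[-1L]) <= 0, FALSE) &
    c(FALSE, rep(TRUE, n - 2L), FALSE)
  peaks <- which(is_max & w >= lo & w <= hi)
  if (!length(peaks))
    return(list(present = FALSE, peak_cm1 = NA_real_, prominence = 0,
                band_amplitude = 0, noise_sd = sig))
  prom <- vapply(peaks, function(i) peak_prominence(y, i), numeric(1))
  best <- which.max(prom)
  present <- prom[best] >= window$min_prominence * spec_max
  # matched-filter gate at the window centre on the raw samples
  amp <- NA_real_
  if (present && sig > 0) {
    sb <- window$template_fwhm_cm1 / (2 * sqrt(2 * log(2)))
    idx <- which(w0 >= window$center_cm1 - 4 * sb &
                   w0 <= window$center_cm1 + 4 * sb)
    if (length(idx) >= 6L) {
      X <- cbind(1, w0[idx] - window$center_cm1,
                 exp(-(w0[idx] - window$center_cm1)^2 / (2 * sb^2)))
      XtXi <- solve(crossprod(X))
      amp <- drop(XtXi %*% crossprod(X, y0[idx]))[3L]
      present <- amp >= window$noise_k * sig * sqrt(XtXi[3L, 3L])
    }
  }
  list(present = present, peak_cm1 = w[peaks[best]], prominence = prom[best],
       band_amplitude = amp, noise_sd = sig)
}

# topographic prominence of peak i: height above the higher of the two key
# saddles (lowest point on each side before reaching higher terrain or the
# spectrum end)
peak_prominence <- function(y, i) {
  h <- y[i]
  left <- y[seq_len(i - 1L)]
  right <- y[(i + 1L):length(y)]
  kl <- {
    higher <- which(left > h)
    if (length(higher)) min(left[max(higher):length(left)]) else min(left)
  }
  kr <- {
    higher <- which(right > h)
    if (length(higher)) min(right[seq_len(min(higher))]) else min(right)
  }
  h - max(kl, kr)
}

#' Composition-call configuration
#'
#' @param ce_fraction_min pooled cholesteryl-ester fraction above which a
#'   spectrum is CE dominated (default 0.5).
#' @param residual_max residual RMS above which an undominated spectrum is
#'   INDETERMINATE rather than AMORPHOUS_LIPID (default 0.15, units of the
#'   peak-normalized spectrum).
#' @param unsaturation_window [band_window] for the =C-H band (3010 +/- 20).
#' @param ester_window [band_window] for the ester carbonyl (1740 +/- 20).
#' @export
composition_config <- function(ce_fraction_min = 0.5,
                               residual_max = 0.15,
                               unsaturation_window = band_window(3010, 20, 0.05),
                               ester_window = band_window(1740, 20, 0.05)) {
  structure(list(ce_fraction_min = ce_fraction_min, residual_max = residual_max,
                 unsaturation_window = unsaturation_window,
                 ester_window = ester_window),
            class = "composition_config")
}

#' Call the composition of an ROI spectrum
#'
#' Baseline (spectrum minimum) is subtracted, the spectrum peak-normalized
#' and decomposed against the library by NNLS; the dominant class is then
#' assigned by rules applied in order: CE_DOMINANT when the pooled oleate +
#' linoleate fraction exceeds `ce_fraction_min`; FREE_CHOLESTEROL when the
#' monohydrate fraction exceeds 0.5; PROTEIN when the protein fraction
#' exceeds 0.5; otherwise AMORPHOUS_LIPID when the fit residual is small,
#' else INDETERMINATE. The 3010 cm-1 unsaturation flag is attached on
#' CH-stretch axes and the 1740 cm-1 ester flag on fingerprint axes.
#'
#' @param sp a [spectrum] covering the CH-stretch (around 3010 cm-1) and/or
#'   fingerprint (around 1740 cm-1) diagnostic region.
#' @param library a [reference_library] on a matching axis.
#' @param config a [composition_config].
#' @return object of class `composition_call`: `coefficients`, `fractions`,
#'   `residual_rms`, `unsaturation_band_present`, `ester_band_present`
#'   (NA off the fingerprint axis), `dominant_class`.
#' @export
classify_composition <- function(sp, library, config = composition_config()) {
  uw <- config$unsaturation_window; ew <- config$ester_window
  covers <- function(win) min(sp$wavenumbers_cm1) <= win$center_cm1 - win$half_width_cm1 &&
    max(sp$wavenumbers_cm1) >= win$center_cm1 + win$half_width_cm1
  on_ch <- covers(uw); on_fp <- covers(ew)
  stop_if(!on_ch && !on_fp,
          fmt("axis %g-%g cm-1 covers neither the 3010 nor the 1740 cm-1 diagnostic region",
              min(sp$wavenumbers_cm1), max(sp$wavenumbers_cm1)))
  y <- sp$intensities - min(sp$intensities)
  stop_if(max(y) <= 0, "spectrum is constant")
  sp_n <- spectrum(sp$wavenumbers_cm1, y / max(y), sp$label)
  dec <- decompose_spectrum(sp_n, library, normalize = TRUE)
  fr <- dec$fractions
  ce <- sum(fr[c("CHOLESTERYL_OLEATE", "CHOLESTERYL_LINOLEATE")], na.rm = TRUE)
  dominant <- if (ce > config$ce_fraction_min) "CE_DOMINANT"
  else if (isTRUE(fr["CHOLESTEROL_MONOHYDRATE"] > 0.5)) "FREE_CHOLESTEROL"
  else if (isTRUE(fr["PROTEIN"] > 0.5)) "PROTEIN"
  else if (dec$residual_rms < config$residual_max) "AMORPHOUS_LIPID"
  else "INDETERMINATE"
  unsat <- if (on_ch) detect_band(sp_n, uw)$present else NA
  ester <- if (on_fp) detect_band(sp_n, ew)$present else NA
  structure(list(coefficients = dec$coefficients, fractions = fr,
                 residual_rms = dec$residual_rms,
                 unsaturation_band_present = unsat,
                 ester_band_present = ester,
                 dominant_class = dominant),
            class = "composition_call")
}

#' @export
print.composition_call <- function(x, ...) {
  cat(fmt("<composition_call> %s (residual RMS %.3g)\n", x$dominant_class,
          x$residual_rms))
  fr <- round(x$fractions, 3)
  cat("  fractions:", paste(names(fr), fr, sep = "=", collapse = ", "), "\n")
  cat(fmt("  unsaturation band (3010): %s; ester band (1740): %s\n",
          x$unsaturation_band_present, x$ester_band_present))
  invisible(x)
}
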