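# Synthetic scenes with exact ground truth: SHG needle fields, hyperspectral
# cubes built from a parametric Gaussian band model of the reference species,
# and reflectance plaque sections. Every generator is a pure function of its
# parameters including the seed.

REFERENCE_SPECIES <- c("CHOLESTEROL_MONOHYDRATE", "CHOLESTERYL_OLEATE",
                       "CHOLESTERYL_LINOLEATE", "PROTEIN")

SCENE_CLASSES <- c("BACKGROUND", "PROTEIN", "AMORPHOUS_LIPID",
                   "CE_CRYSTAL_LINOLEATE", "CE_CRYSTAL_OLEATE", "FC_CRYSTAL")

#' Default vibrational band table
#'
#' Gaussian band parameters (centre, FWHM, relative amplitude) per reference
#' species, spanning the CH-stretch window (2800-3100 cm-1) and the
#' fingerprint window (< 1800 cm-1). Anchored assignments: the CH2 stretch at
#' 2845 cm-1 for cholesteryl esters, the =C-H band near 3010 cm-1 of
#' unsaturated acyl chains (stronger for linoleate, two double bonds, than
#' oleate, one), and the ester carbonyl at 1740 cm-1 carried by both esters
#' but absent from cholesterol monohydrate. The fingerprint window adds the
#' sterol C=C stretch of free cholesterol near 1674 cm-1, the protein amide I
#' band near 1658 cm-1 and a weak acyl C=C stretch near 1660 cm-1 for the
#' esters, so that every species has a response on both diagnostic axes.
#'
#' Band widths reflect physical state: crystalline cholesterol monohydrate
#' has sharp bands (FWHM 14-26 cm-1, including the sterol ring CH stretch
#' near 2907 cm-1), the esters broader acyl-chain bands with a narrow CH2
#' feature near 2870 cm-1, and amorphous protein the broadest profile with
#' a CH3 shoulder near 2975 cm-1. These secondary features are what make
#' the four species spectrally identifiable at realistic noise levels.
#'
#' @return named list of data frames with columns `center_cm1`, `fwhm_cm1`,
#'   `amplitude`.
#' @export
default_band_table <- function() {
  bt <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(center_cm1 = m[, 1], fwhm_cm1 = m[, 2], amplitude = m[, 3])
  }
  list(
    CHOLESTEROL_MONOHYDRATE = bt(2850, 18, 1.0,
                                 2880, 22, 0.7,
                                 2907, 14, 0.5,
                                 2935, 26, 0.45,
                                 1674, 16, 0.30),
    CHOLESTERYL_OLEATE = bt(2845, 30, 1.0,
                            2870, 16, 0.35,
                            2885, 36, 0.6,
                            3003, 18, 0.18,
                            1740, 20, 0.5,
                            1660, 20, 0.12),
    CHOLESTERYL_LINOLEATE = bt(2845, 30, 1.0,
                               2870, 16, 0.35,
                               2885, 36, 0.6,
                               3012, 24, 0.42,
                               1740, 20, 0.5,
                               1660, 22, 0.25),
    PROTEIN = bt(2930, 50, 1.0,
                 2960, 40, 0.5,
                 2975, 18, 0.25,
                 1658, 38, 0.85)
  )
}

#' Synthesize a reference spectrum from the band table
#'
#' Sum of Gaussian bands evaluated on the axis, peak-normalized so the
#' maximum on that axis is 1.
#'
#' @param species one of `r paste(REFERENCE_SPECIES, collapse = ", ")`.
#' @param axis a [wavenumber_axis].
#' @param band_table band table as from [default_band_table()].
#' @return a [spectrum] labelled with the species name.
#' @export
synth_reference_spectrum <- function(species, axis,
                                     band_table = default_band_table()) {
  stop_if(!species %in% names(band_table),
          fmt("unknown species '%s' (band table has: %s)", species,
              paste(names(band_table), collapse = ", ")))
  w <- axis_values(axis)
  bands <- band_table[[species]]
  y <- rep(0, length(w))
  for (i in seq_len(nrow(bands))) {
    sigma <- bands$fwhm_cm1[i] / (2 * sqrt(2 * log(2)))
    y <- y + bands$amplitude[i] * exp(-(w - bands$center_cm1[i])^2 / (2 * sigma^2))
  }
  stop_if(max(y) < 1e-9,
          fmt("species '%s' has no spectral response on axis %g-%g cm-1",
              species, axis$start_cm1, axis$stop_cm1))
  spectrum(w, y / max(y), species)
}

# ---- needle fields ----------------------------------------------------------

#' Parameters for a synthetic SHG needle field
#'
#' Defaults emulate the study's acquisition geometry: 512 x 512 frames of
#' bright needle-like crystals on a dark background. Needle lengths are drawn
#' in micrometres from a fixed, gamma or lognormal family; needles are
#' rendered as anti-aliased rotated rectangles and kept pixel-disjoint with a
#' small separation margin unless `allow_overlap`. Forced crossing pairs
#' intersect near their midpoints at an angle drawn from
#' `crossing_angle_range_deg` (default 30-90 degrees, the unambiguous
#' crossing regime).
#'
#' @param image_shape integer (rows, cols).
#' @param pixel_size_um physical pixel size, micrometres.
#' @param n_needles number of independent (non-crossing) needles.
#' @param length_um list: `family` in `"FIXED"`, `"GAMMA"`, `"LOGNORMAL"` and
#'   its parameters (`value`; `shape`/`scale`; `meanlog`/`sdlog`), plus
#'   optional truncation `min`/`max` in micrometres.
#' @param width_px needle width in pixels (>= 1).
#' @param intensity_amplitude needle amplitude above background.
#' @param background_level constant background intensity.
#' @param noise_sd additive Gaussian noise sd, image-intensity units.
#' @param allow_overlap allow independent needles to overlap.
#' @param n_forced_crossing_pairs number of crossing pairs to add.
#' @param crossing_angle_range_deg range the crossing angle is drawn from.
#' @param min_separation_px minimum pixel separation between distinct objects.
#' @param max_place_attempts placement retries before giving up.
#' @param seed RNG seed.
#' @return list of class `needle_field_params`.
#' @export
needle_field_params <- function(image_shape = c(512L, 512L),
                                pixel_size_um = 0.5,
                                n_needles = 40L,
                                length_um = list(family = "GAMMA", shape = 4,
                                                 scale = 3, min = 5, max = 30),
                                width_px = 3,
                                intensity_amplitude = 50,
                                background_level = 10,
                                noise_sd = 0,
                                allow_overlap = FALSE,
                                n_forced_crossing_pairs = 0L,
                                crossing_angle_range_deg = c(30, 90),
                                min_separation_px = 3,
                                max_place_attempts = 500L,
                                seed = 1L) {
  stop_if(n_needles < 0 || n_forced_crossing_pairs < 0, "counts must be >= 0")
  stop_if(width_px < 1, "width_px must be >= 1")
  stop_if(intensity_amplitude <= 0, "intensity_amplitude must be positive")
  stop_if(background_level < 0 || noise_sd < 0,
          "background_level and noise_sd must be >= 0")
  structure(as.list(environment()), class = "needle_field_params")
}

sample_lengths_um <- function(spec, n) {
  fam <- toupper(spec$family %||% "FIXED")
  draw <- switch(fam,
    FIXED = rep(spec$value, n),
    GAMMA = stats::rgamma(n, shape = spec$shape, scale = spec$scale),
    LOGNORMAL = stats::rlnorm(n, meanlog = spec$meanlog, sdlog = spec$sdlog),
    stop(fmt("unknown length distribution family '%s'", fam), call. = FALSE))
  lo <- spec$min %||% -Inf
  hi <- spec$max %||% Inf
  pmin(pmax(draw, lo), hi)
}

# Anti-aliased coverage of a rotated rectangle (needle) on the pixel grid:
# separable linear edge profile, coverage in [0,1]; exact in the interior.
needle_coverage <- function(shape, center, theta_deg, length_px, width_px) {
  th <- theta_deg * pi / 180
  u <- c(cos(th), sin(th))
  rpad <- ceiling(length_px / 2 + width_px + 2)
  r0 <- max(1L, floor(center[1L] - rpad)); r1 <- min(shape[1L], ceiling(center[1L] + rpad))
  c0 <- max(1L, floor(center[2L] - rpad)); c1 <- min(shape[2L], ceiling(center[2L] + rpad))
  if (r0 > r1 || c0 > c1) return(NULL)
  rows <- r0:r1; cols <- c0:c1
  dr <- outer(rows - center[1L], rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - center[2L])
  du <- dr * u[1L] + dc * u[2L]
  dv <- -dr * u[2L] + dc * u[1L]
  cov <- pmin(pmax(length_px / 2 + 0.5 - abs(du), 0), 1) *
    pmin(pmax(width_px / 2 + 0.5 - abs(dv), 0), 1)
  list(rows = rows, cols = cols, cov = cov)
}

coverage_pixels <- function(patch, min_cov = 0.5) {
  idx <- which(patch$cov >= min_cov, arr.ind = TRUE)
  cbind(row = patch$rows[idx[, 1L]], col = patch$cols[idx[, 2L]])
}

#' Generate a synthetic SHG needle field with exact ground truth
#'
#' Needles are anti-aliased rotated rectangles of the sampled length and
#' width at `intensity_amplitude` over `background_level`; i.i.d. Gaussian
#' noise of sd `noise_sd` is added last. Ground truth records every needle's
#' centre, orientation, true length, width and pixel set (coverage >= 0.5),
#' plus the index pairs of forced crossings, which are rendered as two
#' needles intersecting near their midpoints.
#'
#' @param params a [needle_field_params].
#' @return list with `image` (an [intensity_image], channel SHG) and
#'   `truth` (list: `needles` data frame, `pixel_sets`, `crossing_pairs`).
#' @export
generate_needle_field <- function(params) {
  stopifnot(inherits(params, "needle_field_params"))
  p <- params
  with_seed(p$seed, {
    shape <- as.integer(p$image_shape)
    img <- matrix(p$background_level, shape[1L], shape[2L])
    occupied <- matrix(FALSE, shape[1L], shape[2L])
    needles <- list()
    pixel_sets <- list()
    crossing_pairs <- matrix(integer(0), 0L, 2L)

    sep <- max(0, p$min_separation_px)
    place_one <- function(theta = NULL, center = NULL, length_um = NULL,
                          ignore_occupancy = FALSE) {
      for (attempt in seq_len(p$max_place_attempts)) {
        L_um <- length_um %||% sample_lengths_um(p$length_um, 1L)
        L_px <- L_um / p$pixel_size_um
        th <- theta %||% stats::runif(1, 0, 180)
        margin <- L_px / 2 + p$width_px + 2
        if (2 * margin >= min(shape)) stop("needle too long for the image", call. = FALSE)
        ctr <- center %||% c(stats::runif(1, 1 + margin, shape[1L] - margin),
                             stats::runif(1, 1 + margin, shape[2L] - margin))
        patch <- needle_coverage(shape, ctr, th, L_px, p$width_px)
        px <- coverage_pixels(patch)
        if (nrow(px) == 0L) next
        if (min(px) < 1L || max(px[, 1L]) > shape[1L] || max(px[, 2L]) > shape[2L]) next
        if (!p$allow_overlap && !ignore_occupancy) {
          rr <- pmax(1L, px[, 1L] - sep); r2 <- pmin(shape[1L], px[, 1L] + sep)
          free <- TRUE
          for (k in seq_len(nrow(px))) {
            cc <- max(1L, px[k, 2L] - sep):min(shape[2L], px[k, 2L] + sep)
            if (any(occupied[rr[k]:r2[k], cc])) { free <- FALSE; break }
          }
          if (!free) next
        }
        return(list(center = ctr, theta = th, length_um = L_um,
                    length_px = L_px, patch = patch, px = px))
      }
      stop(fmt(paste0("could not place a needle without overlap after %d ",
                      "attempts (reduce n_needles, lengths, or separation)"),
               p$max_place_attempts), call. = FALSE)
    }

    add_needle <- function(nd) {
      i <- length(needles) + 1L
      needles[[i]] <<- data.frame(
        index = i, center_row = nd$center[1L], center_col = nd$center[2L],
        orientation_deg = nd$theta %% 180, true_length_um = nd$length_um,
        true_width_px = p$width_px)
      pixel_sets[[i]] <<- nd$px
      img[nd$patch$rows, nd$patch$cols] <<-
        img[nd$patch$rows, nd$patch$cols] + p$intensity_amplitude * nd$patch$cov
      occupied[nd$px] <<- TRUE
      i
    }

    for (i in seq_len(p$n_needles)) add_needle(place_one())

    for (k in seq_len(p$n_forced_crossing_pairs)) {
      placed <- FALSE
      for (try_k in seq_len(p$max_place_attempts)) {
        a <- place_one()
        dth <- stats::runif(1, p$crossing_angle_range_deg[1L],
                            p$crossing_angle_range_deg[2L])
        jitter <- stats::runif(2, -1.5, 1.5)
        b <- tryCatch(
          place_one(theta = a$theta + dth, center = a$center + jitter,
                    length_um = if (identical(toupper(p$length_um$family), "FIXED"))
                      a$length_um else NULL,
                    ignore_occupancy = TRUE),
          error = function(e) NULL)
        if (is.null(b)) next
        # the pair must genuinely intersect and stay clear of earlier objects
        shared <- nrow(merge(as.data.frame(a$px), as.data.frame(b$px)))
        if (shared < 1L) next
        bb <- b$px
        rr <- pmax(1L, bb[, 1L] - sep); r2 <- pmin(shape[1L], bb[, 1L] + sep)
        clear <- TRUE
        for (kk in seq_len(nrow(bb))) {
          cc <- max(1L, bb[kk, 2L] - sep):min(shape[2L], bb[kk, 2L] + sep)
          if (any(occupied[rr[kk]:r2[kk], cc])) { clear <- FALSE; break }
        }
        if (!clear) next
        ia <- add_needle(a)
        ib <- add_needle(b)
        crossing_pairs <- rbind(crossing_pairs, c(ia, ib))
        placed <- TRUE
        break
      }
      stop_if(!placed,
              fmt("could not place crossing pair %d after %d attempts", k,
                  p$max_place_attempts))
    }

    if (p$noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, p$noise_sd),
                          shape[1L], shape[2L])

    truth <- list(
      needles = if (length(needles)) do.call(rbind, needles) else
        data.frame(index = integer(0)),
      pixel_sets = pixel_sets,
      crossing_pairs = crossing_pairs)
    list(image = intensity_image(img, p$pixel_size_um, "SHG"), truth = truth)
  })
}

# ---- spectral scenes --------------------------------------------------------

#' Spectral scene: per-pixel class or mixture ground truth
#'
#' @param class_map character matrix over
#'   `r paste(SCENE_CLASSES, collapse = ", ")`.
#' @param mixture_map optional array (row, col, species) of non-negative
#'   weights summing to 1 per pixel; overrides `class_map` where given.
#' @param noise_sd additive Gaussian noise sd per channel.
#' @param seed RNG seed.
#' @export
spectral_scene <- function(class_map, mixture_map = NULL, noise_sd = 0,
                           seed = 1L) {
  stop_if(!is.matrix(class_map), "class_map must be a matrix")
  bad <- setdiff(unique(as.vector(class_map)), SCENE_CLASSES)
  stop_if(length(bad) > 0,
          fmt("unknown scene class(es): %s", paste(bad, collapse = ", ")))
  if (!is.null(mixture_map)) {
    stop_if(length(dim(mixture_map)) != 3L ||
              any(dim(mixture_map)[1:2] != dim(class_map)),
            "mixture_map must be (row, col, species) matching class_map")
    stop_if(any(mixture_map < 0), "mixture weights must be non-negative")
    sums <- apply(mixture_map, c(1, 2), sum)
    stop_if(any(abs(sums - 1) > 1e-9 & sums > 0),
            "mixture weights must sum to 1 per pixel")
  }
  structure(list(class_map = class_map, mixture_map = mixture_map,
                 noise_sd = noise_sd, seed = seed), class = "spectral_scene")
}

# class -> weights over REFERENCE_SPECIES; amorphous lipid is modelled as a
# CH2-rich droplet mixture of the two esters
class_weights <- function(class) {
  w <- stats::setNames(rep(0, length(REFERENCE_SPECIES)), REFERENCE_SPECIES)
  switch(class,
    BACKGROUND = w,
    PROTEIN = { w["PROTEIN"] <- 1; w },
    AMORPHOUS_LIPID = { w["CHOLESTERYL_OLEATE"] <- 0.8
                        w["CHOLESTERYL_LINOLEATE"] <- 0.2; w },
    CE_CRYSTAL_LINOLEATE = { w["CHOLESTERYL_LINOLEATE"] <- 1; w },
    CE_CRYSTAL_OLEATE = { w["CHOLESTERYL_OLEATE"] <- 1; w },
    FC_CRYSTAL = { w["CHOLESTEROL_MONOHYDRATE"] <- 1; w },
    stop(fmt("scene class '%s' has no species mapping", class), call. = FALSE))
}

#' Generate a hyperspectral cube from a spectral scene
#'
#' Every pixel's spectrum is the weighted sum of the peak-normalized
#' reference spectra for its class (or mixture weights), plus i.i.d.
#' Gaussian noise; generation is exactly linear in the references at zero
#' noise.
#'
#' @param scene a [spectral_scene].
#' @param axis a [wavenumber_axis].
#' @param band_table band table as from [default_band_table()].
#' @param pixel_size_um physical pixel size in micrometres.
#' @return list with `cube` (a [hyperspectral_cube]) and `scene` (ground
#'   truth, unchanged).
#' @export
generate_cube <- function(scene, axis, band_table = default_band_table(),
                          pixel_size_um = 0.5) {
  stopifnot(inherits(scene, "spectral_scene"))
  refs <- sapply(REFERENCE_SPECIES, function(s)
    synth_reference_spectrum(s, axis, band_table)$intensities)
  shape <- dim(scene$class_map)
  nc <- n_channels(axis)
  arr <- array(0, c(shape, nc))
  W <- matrix(0, prod(shape), length(REFERENCE_SPECIES))
  for (cl in unique(as.vector(scene$class_map))) {
    idx <- which(scene$class_map == cl)
    W[idx, ] <- matrix(class_weights(cl), length(idx),
                       length(REFERENCE_SPECIES), byrow = TRUE)
  }
  if (!is.null(scene$mixture_map)) {
    mm <- matrix(scene$mixture_map, prod(shape), length(REFERENCE_SPECIES))
    use <- rowSums(mm) > 0
    W[use, ] <- mm[use, ]
  }
  flat <- W %*% t(refs)                       # (pixel, channel)
  arr <- array(flat, c(shape, nc))
  if (scene$noise_sd > 0)
    arr <- with_seed(scene$seed,
                     arr + array(stats::rnorm(length(arr), 0, scene$noise_sd),
                                 dim(arr)))
  list(cube = hyperspectral_cube(arr, axis, pixel_size_um), scene = scene)
}

# ---- reflectance sections ---------------------------------------------------

#' Generate a synthetic reflectance section with known crystal burden
#'
#' A dim elliptical plaque body on a dark exterior, with bright crystal
#' specks covering exactly `round(crystal_fraction * n_plaque_pixels)` plaque
#' pixels. Specks are grown from random seeds inside the plaque and trimmed
#' to the exact target count. Returns the image plus plaque and crystal
#' masks as ground truth.
#'
#' @param shape integer (rows, cols).
#' @param plaque_ellipse list with `center` (row, col) and `radii` (row, col
#'   semi-axes in pixels); must lie inside the image.
#' @param crystal_fraction target crystal area fraction in `[0, 1]`.
#' @param seed RNG seed.
#' @param pixel_size_um physical pixel size in micrometres.
#' @param levels intensity levels: `exterior`, `plaque`, `crystal`.
#' @param noise_sd additive Gaussian noise sd.
#' @return list: `image` (channel REFLECTANCE), `plaque_mask`, `crystal_mask`.
#' @export
generate_reflectance_section <- function(shape = c(256L, 256L),
                                         plaque_ellipse = list(center = c(128, 128),
                                                               radii = c(90, 70)),
                                         crystal_fraction = 0.1,
                                         seed = 1L,
                                         pixel_size_um = 1,
                                         levels = c(exterior = 2, plaque = 30,
                                                    crystal = 200),
                                         noise_sd = 1) {
  stop_if(!is_scalar_num(crystal_fraction) || crystal_fraction < 0 ||
            crystal_fraction > 1, "crystal_fraction must be in [0, 1]")
  ctr <- plaque_ellipse$center; rad <- plaque_ellipse$radii
  stop_if(ctr[1L] - rad[1L] < 1 || ctr[1L] + rad[1L] > shape[1L] ||
            ctr[2L] - rad[2L] < 1 || ctr[2L] + rad[2L] > shape[2L],
          "plaque ellipse must lie inside the image")
  rr <- matrix(seq_len(shape[1L]), shape[1L], shape[2L])
  cc <- matrix(seq_len(shape[2L]), shape[1L], shape[2L], byrow = TRUE)
  plaque <- ((rr - ctr[1L]) / rad[1L])^2 + ((cc - ctr[2L]) / rad[2L])^2 <= 1
  n_plaque <- sum(plaque)
  target <- round(crystal_fraction * n_plaque)
  crystal <- matrix(FALSE, shape[1L], shape[2L])
  with_seed(seed, {
    plaque_idx <- which(plaque)
    while (sum(crystal) < target) {
      seed_px <- arrayInd(sample(plaque_idx, 1L), shape)
      r <- stats::runif(1, 1, 2.5)
      rows <- max(1, floor(seed_px[1] - r)):min(shape[1L], ceiling(seed_px[1] + r))
      cols <- max(1, floor(seed_px[2] - r)):min(shape[2L], ceiling(seed_px[2] + r))
      for (i in rows) for (j in cols) {
        if (plaque[i, j] && !crystal[i, j] &&
            (i - seed_px[1])^2 + (j - seed_px[2])^2 <= r^2) {
          if (sum(crystal) >= target) break
          crystal[i, j] <- TRUE
        }
      }
    }
    img <- matrix(levels[["exterior"]], shape[1L], shape[2L])
    img[plaque] <- levels[["plaque"]]
    img[crystal] <- levels[["crystal"]]
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                          shape[1L], shape[2L])
    list(image = intensity_image(img, pixel_size_um, "REFLECTANCE"),
         plaque_mask = plaque, crystal_mask = crystal)
  })
}
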