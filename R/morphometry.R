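# SHG needle morphometry: Otsu binarization, marker-controlled watershed
# splitting of touching crystals, rejection of overlapping objects, and
# count / density / length reporting.

#' Otsu threshold of an intensity image
#'
#' Maximizes the between-class variance over a 256-bin histogram spanning
#' the image's `[min, max]` intensity range; the mask keeps pixels strictly
#' above the selected threshold (the upper edge of the background bin). Ties
#' resolve to the lowest maximizing threshold.
#'
#' @param image an [intensity_image] or numeric matrix with at least two
#'   distinct values.
#' @param n_bins histogram resolution (default 256).
#' @return list with `threshold` and logical `mask`.
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  m <- if (inherits(image, "intensity_image")) image$pixels else image
  stop_if(!is.matrix(m) || !is.numeric(m), "image must be numeric")
  lo <- min(m); hi <- max(m)
  stop_if(hi <= lo, "degenerate histogram: image has a single intensity value")
  # bin pixels; value == hi lands in the top bin
  bin <- pmin(floor((m - lo) / (hi - lo) * n_bins) + 1L, n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  p <- counts / length(m)
  omega <- cumsum(p)                      # class-0 weight up to bin k
  mu <- cumsum(p * seq_len(n_bins))       # first moment in bin units
  mu_t <- mu[n_bins]
  k <- seq_len(n_bins - 1L)
  valid <- omega[k] > 0 & omega[k] < 1
  sigma_b2 <- rep(-Inf, n_bins - 1L)
  sigma_b2[valid] <- (mu_t * omega[k][valid] - mu[k][valid])^2 /
    (omega[k][valid] * (1 - omega[k][valid]))
  k_star <- which.max(sigma_b2)           # first maximum on ties
  threshold <- lo + k_star * (hi - lo) / n_bins
  list(threshold = threshold, mask = m > threshold)
}

#' Split touching crystals by watershed on the distance transform
#'
#' The foreground is partitioned by watershed on the negated Euclidean
#' distance transform with markers at the h-maxima of the distance
#' transform (tolerance `h_maxima`). Every foreground pixel receives exactly
#' one label; labels are contiguous from 1.
#'
#' @param binary_mask logical matrix.
#' @param h_maxima minimum distance-transform height separating markers
#'   (pixels; default 1).
#' @return integer label matrix (0 = background).
#' @export
watershed_split <- function(binary_mask, h_maxima = 1) {
  stop_if(!is.matrix(binary_mask) || !is.logical(binary_mask),
          "binary_mask must be a logical matrix")
  if (!any(binary_mask)) {
    warning("empty mask: nothing to segment", call. = FALSE)
    return(matrix(0L, nrow(binary_mask), ncol(binary_mask)))
  }
  dm <- EBImage::distmap(EBImage::Image(binary_mask * 1))
  ws <- EBImage::watershed(dm, tolerance = h_maxima, ext = 1L)
  lab <- matrix(as.integer(EBImage::imageData(ws)), nrow(binary_mask))
  # relabel contiguously from 1 in first-appearance order
  ids <- sort(unique(lab[lab > 0L]))
  if (length(ids) && !identical(ids, seq_along(ids))) {
    remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}

#' Morphometry configuration
#'
#' Tunables of the Fig.-3-style pipeline, all surfaced here: the
#' watershed marker depth, the minimum object size (speck filter), the
#' pairwise rectangle-overlap threshold, and the rectangle fill fraction
#' below which an object is treated as a bundle of overlapping needles and
#' split along its dominant axes.
#'
#' @param overlap_fraction_max objects whose oriented bounding rectangle
#'   overlaps other objects' rectangles by more than this fraction of its
#'   own area fail as overlapping (default 0.2).
#' @param fill_fraction_min objects filling less than this fraction of their
#'   minimum-area oriented rectangle are composite (overlapping) objects
#'   (default 0.55; isolated straight needles fill >= ~0.7).
#' @param min_object_px objects below this pixel count fail as specks
#'   (default 8).
#' @param h_maxima watershed marker depth in pixels (default 1).
#' @param split_composites split composite objects into two needle parts
#'   before reporting (default TRUE); parts keep FAILED_OVERLAP status.
#' @param denoise_sigma sd (pixels) of the Gaussian filter applied before
#'   thresholding (default 1; 0 disables). Stabilizes the binary mask and
#'   the distance transform against pixel noise, playing the role of the
#'   frame averaging used at acquisition time.
#' @return list of class `morphometry_config`.
#' @export
morphometry_config <- function(overlap_fraction_max = 0.2,
                               fill_fraction_min = 0.55,
                               min_object_px = 8L,
                               h_maxima = 1,
                               split_composites = TRUE,
                               denoise_sigma = 1) {
  stop_if(overlap_fraction_max < 0, "overlap_fraction_max must be >= 0")
  stop_if(fill_fraction_min < 0 || fill_fraction_min > 1,
          "fill_fraction_min must be in [0, 1]")
  structure(list(overlap_fraction_max = overlap_fraction_max,
                 fill_fraction_min = fill_fraction_min,
                 min_object_px = as.integer(min_object_px),
                 h_maxima = h_maxima,
                 split_composites = isTRUE(split_composites),
                 denoise_sigma = denoise_sigma),
            class = "morphometry_config")
}

# Split a composite (overlapping) object into its two dominant needle parts.
# Candidate axes are chords between convex-hull vertices / edge midpoints;
# the best axis maximizes the pixel count within the half-width estimated
# from the distance transform; remaining pixels vote for the second axis.
split_composite_object <- function(px, edt_vals) {
  half_w <- as.numeric(stats::quantile(edt_vals, 0.9)) + 0.5
  hp <- hull_points(px)
  mids <- (hp + hp[c(seq_len(nrow(hp))[-1L], 1L), , drop = FALSE]) / 2
  cand <- rbind(hp, mids)
  n_cand <- nrow(cand)
  score_line <- function(a, b) {
    d <- b - a; L <- sqrt(sum(d^2))
    if (L < 1e-9) return(NULL)
    d <- d / L
    dist <- abs((px[, 1L] - a[1L]) * (-d[2L]) + (px[, 2L] - a[2L]) * d[1L])
    list(n = sum(dist <= half_w), within = dist <= half_w, dist = dist)
  }
  best_over <- function(restrict_pts) {
    hp2 <- hull_points(restrict_pts)
    mids2 <- (hp2 + hp2[c(seq_len(nrow(hp2))[-1L], 1L), , drop = FALSE]) / 2
    cc <- rbind(hp2, mids2)
    best <- NULL
    nn <- nrow(cc)
    for (i in seq_len(nn - 1L)) for (j in (i + 1L):nn) {
      s <- score_line(cc[i, ], cc[j, ])
      if (!is.null(s) && (is.null(best) || s$n > best$n)) best <- s
    }
    best
  }
  b1 <- best_over(px)
  if (is.null(b1)) return(NULL)
  rem <- px[!b1$within, , drop = FALSE]
  if (nrow(rem) < 3L) return(NULL)
  b2 <- best_over(rem)
  if (is.null(b2)) return(NULL)
  in1 <- b1$within & (!b2$within | b1$dist <= b2$dist)
  in2 <- b2$within & !in1
  leftover <- !(in1 | in2)
  # park stray pixels with the nearer axis so the partition is complete
  if (any(leftover)) {
    to1 <- b1$dist[leftover] <= b2$dist[leftover]
    in1[leftover] <- to1
    in2[leftover] <- !to1
  }
  if (sum(in1) < 3L || sum(in2) < 3L) return(NULL)
  list(px[in1, , drop = FALSE], px[in2, , drop = FALSE])
}

#' Reject overlapping and undersized needle objects
#'
#' For every labelled object the minimum-area oriented bounding rectangle is
#' fitted. An object fails as overlapping when (a) its rectangle intersects
#' other objects' rectangles by more than `overlap_fraction_max` of its own
#' rectangle area, or (b) its pixels fill less than `fill_fraction_min` of
#' its rectangle -- the signature of two or more needles crossing inside one
#' connected component, which watershed on the distance transform cannot
#' separate (the junction is the distance maximum). Composite objects are
#' split into their two dominant needle parts, both retained with status
#' `FAILED_OVERLAP`. Objects below `min_object_px` fail as `FAILED_SIZE`.
#'
#' @param labeled_mask integer label matrix from [watershed_split()].
#' @param pixel_size_um physical pixel size in micrometres.
#' @param config a [morphometry_config].
#' @return list with `objects` (data frame: label, pixel_count, length_um,
#'   orientation_deg, centroid_row, centroid_col, fill_fraction,
#'   overlap_fraction, status) and `pixel_sets` (list of n x 2 matrices).
#' @export
reject_overlaps <- function(labeled_mask, pixel_size_um,
                            config = morphometry_config()) {
  stop_if(!is.matrix(labeled_mask), "labeled_mask must be a matrix")
  labs <- sort(unique(labeled_mask[labeled_mask > 0L]))
  pixel_sets <- list()
  status <- character(0)
  composite <- logical(0)
  if (length(labs)) {
    mask <- labeled_mask > 0L
    edt <- matrix(as.numeric(EBImage::imageData(
      EBImage::distmap(EBImage::Image(mask * 1)))), nrow(labeled_mask))
    all_px <- which(mask, arr.ind = TRUE)
    lab_of <- labeled_mask[all_px]
    for (lb in labs) {
      px <- all_px[lab_of == lb, , drop = FALSE]
      colnames(px) <- c("row", "col")
      if (nrow(px) < config$min_object_px) {
        pixel_sets <- c(pixel_sets, list(px))
        status <- c(status, "FAILED_SIZE"); composite <- c(composite, FALSE)
        next
      }
      rect <- min_area_rect(px)
      fill <- nrow(px) / rect$area_px2
      if (fill < config$fill_fraction_min) {
        parts <- if (config$split_composites && nrow(px) >= 2L * config$min_object_px)
          split_composite_object(px, edt[px]) else NULL
        if (is.null(parts)) {
          pixel_sets <- c(pixel_sets, list(px))
          status <- c(status, "FAILED_OVERLAP"); composite <- c(composite, TRUE)
        } else {
          for (pp in parts) {
            colnames(pp) <- c("row", "col")
            pixel_sets <- c(pixel_sets, list(pp))
            status <- c(status, "FAILED_OVERLAP"); composite <- c(composite, TRUE)
          }
        }
      } else {
        pixel_sets <- c(pixel_sets, list(px))
        status <- c(status, "CANDIDATE"); composite <- c(composite, FALSE)
      }
    }
  }
  n <- length(pixel_sets)
  rects <- lapply(pixel_sets, min_area_rect)
  overlap_frac <- rep(0, n)
  if (n >= 2L) {
    for (i in seq_len(n)) {
      inter <- 0
      for (j in seq_len(n)) {
        if (i == j) next
        # cheap bounding-circle prefilter
        d <- sqrt(sum((rects[[i]]$center - rects[[j]]$center)^2))
        ri <- sqrt(rects[[i]]$length_px^2 + rects[[i]]$width_px^2) / 2
        rj <- sqrt(rects[[j]]$length_px^2 + rects[[j]]$width_px^2) / 2
        if (d > ri + rj) next
        inter <- inter + convex_intersection_area(rects[[i]]$corners,
                                                  rects[[j]]$corners)
      }
      overlap_frac[i] <- inter / rects[[i]]$area_px2
    }
  }
  final_status <- status
  flag <- status == "CANDIDATE" & overlap_frac > config$overlap_fraction_max
  final_status[flag] <- "FAILED_OVERLAP"
  final_status[final_status == "CANDIDATE"] <- "PASSED"
  objects <- do.call(rbind, lapply(seq_len(n), function(i) {
    px <- pixel_sets[[i]]
    ml <- measure_length(px, pixel_size_um)
    data.frame(label = i, pixel_count = nrow(px),
               length_um = ml$length_um, orientation_deg = ml$orientation_deg,
               centroid_row = mean(px[, 1L]), centroid_col = mean(px[, 2L]),
               fill_fraction = nrow(px) / rects[[i]]$area_px2,
               overlap_fraction = overlap_frac[i],
               status = final_status[i])
  }))
  if (is.null(objects))
    objects <- data.frame(label = integer(0), pixel_count = integer(0),
                          length_um = numeric(0), orientation_deg = numeric(0),
                          centroid_row = numeric(0), centroid_col = numeric(0),
                          fill_fraction = numeric(0),
                          overlap_fraction = numeric(0), status = character(0))
  list(objects = objects, pixel_sets = pixel_sets)
}

#' Run the full needle morphometry pipeline on an SHG image
#'
#' Composes [otsu_threshold()] -> [watershed_split()] -> [reject_overlaps()]
#' -> [measure_length()] and summarizes counts, density and lengths of the
#' passed objects. Density is per analysis area: the full image by default,
#' or the plaque mask area when one is supplied.
#'
#' @param image an [intensity_image].
#' @param config a [morphometry_config].
#' @param plaque_mask optional logical matrix; restricts the analysis area
#'   used for the density denominator.
#' @return object of class `morphometry_result`: `objects` data frame,
#'   `pixel_sets`, `threshold`, `n_objects_total` (before rejection),
#'   `n_passed`, `n_failed_overlap`, `n_failed_size`, `density_per_mm2`,
#'   `length_summary` (mean/median/sd, um, passed objects),
#'   `analysis_area_mm2`, `pixel_size_um`.
#' @export
run_morphometry <- function(image, config = morphometry_config(),
                            plaque_mask = NULL) {
  stop_if(!inherits(image, "intensity_image"), "image must be an intensity_image")
  px <- image$pixels
  if (config$denoise_sigma > 0)
    px <- matrix(as.numeric(EBImage::imageData(EBImage::gblur(
      EBImage::Image(px), sigma = config$denoise_sigma))), nrow(px))
  if (max(px) <= min(px)) {
    # featureless frame (e.g. background only): nothing to segment
    ot <- list(threshold = NA_real_,
               mask = matrix(FALSE, nrow(px), ncol(px)))
    lab <- matrix(0L, nrow(px), ncol(px))
  } else {
    ot <- otsu_threshold(px)
    lab <- watershed_split(ot$mask, h_maxima = config$h_maxima)
  }
  rej <- reject_overlaps(lab, image$pixel_size_um, config)
  obj <- rej$objects
  n_px_area <- if (is.null(plaque_mask)) length(image$pixels) else {
    stop_if(!all(dim(plaque_mask) == dim(image$pixels)),
            "plaque_mask shape must match the image")
    sum(plaque_mask)
  }
  area_mm2 <- n_px_area * image$pixel_size_um^2 / 1e6
  passed <- obj$status == "PASSED"
  lens <- obj$length_um[passed]
  res <- list(
    objects = obj,
    pixel_sets = rej$pixel_sets,
    threshold = ot$threshold,
    n_objects_total = length(unique(lab[lab > 0L])),
    n_passed = sum(passed),
    n_failed_overlap = sum(obj$status == "FAILED_OVERLAP"),
    n_failed_size = sum(obj$status == "FAILED_SIZE"),
    density_per_mm2 = sum(passed) / area_mm2,
    length_summary = list(mean = if (length(lens)) mean(lens) else NA_real_,
                          median = if (length(lens)) stats::median(lens) else NA_real_,
                          sd = if (length(lens) > 1) stats::sd(lens) else NA_real_),
    analysis_area_mm2 = area_mm2,
    pixel_size_um = image$pixel_size_um)
  class(res) <- "morphometry_result"
  res
}

#' @export
print.morphometry_result <- function(x, ...) {
  cat(fmt(paste0("<morphometry_result> %d objects (%d passed, %d overlap-failed,",
                 " %d size-failed)\n  density %.3g /mm^2 over %.3g mm^2;",
                 " mean passed length %.3g um\n"),
          nrow(x$objects), x$n_passed, x$n_failed_overlap, x$n_failed_size,
          x$density_per_mm2, x$analysis_area_mm2, x$length_summary$mean))
  invisible(x)
}

#' Match detected objects to generator ground truth
#'
#' Greedy one-to-one matching by shared pixel count: each ground-truth
#' needle is matched to the detected object sharing the most pixels,
#' requiring at least `min_recall` of the needle's true pixels.
#'
#' @param result a `morphometry_result`.
#' @param truth ground truth from [generate_needle_field()].
#' @param min_recall minimum fraction of true pixels recovered (default 0.3).
#' @return data frame: `gt_index`, `object_label`, `true_length_um`,
#'   `est_length_um`, `status`.
#' @export
match_objects <- function(result, truth, min_recall = 0.3) {
  nr <- max(vapply(result$pixel_sets, function(p) max(p[, 1L], 0L), numeric(1)),
            vapply(truth$pixel_sets, function(p) max(p[, 1L], 0L), numeric(1)), 1)
  key <- function(px) px[, 1L] + (px[, 2L] - 1) * (nr + 1)
  det_keys <- lapply(result$pixel_sets, key)
  taken <- rep(FALSE, length(det_keys))
  rows <- lapply(seq_along(truth$pixel_sets), function(g) {
    gk <- key(truth$pixel_sets[[g]])
    shared <- vapply(seq_along(det_keys), function(i)
      if (taken[i]) 0L else length(intersect(gk, det_keys[[i]])), integer(1))
    best <- which.max(shared)
    if (length(best) == 0L || shared[best] < min_recall * length(gk)) return(NULL)
    taken[best] <<- TRUE
    data.frame(gt_index = g, object_label = result$objects$label[best],
               true_length_um = truth$needles$true_length_um[g],
               est_length_um = result$objects$length_um[best],
               status = result$objects$status[best])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gt_index = integer(0), object_label = integer(0),
                      true_length_um = numeric(0), est_length_um = numeric(0),
                      status = character(0))
  out
}
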