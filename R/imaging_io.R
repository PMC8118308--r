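# On-disk artifacts and conventions: single-channel TIFF images, multi-page
# TIFF hyperspectral cubes with a JSON sidecar carrying the wavenumber axis,
# CSV spectra, and region-of-interest resolution.
#
# Conventions used throughout the package:
#  * pixel coordinates are 1-based (row, col); row increases downward;
#  * physical lengths are micrometres: length_um = pixels * pixel_size_um;
#  * intensities are stored as-is (no normalization at read time); float
#    TIFFs carry a power-of-two intensity scale in a JSON sidecar so that
#    round trips are exact; uint8/uint16 round trips are bit-exact.

CHANNEL_LABELS <- c("SHG", "SRS", "CARS", "REFLECTANCE", "OTHER")

#' Single-channel intensity image
#'
#' Carrier for SHG, SRS, CARS and reflectance frames: a 2-D matrix of finite
#' intensities with a physical pixel size.
#'
#' @param pixels numeric matrix (at least 8 x 8), all values finite.
#' @param pixel_size_um physical size of one pixel in micrometres (> 0).
#' @param channel_label one of `"SHG"`, `"SRS"`, `"CARS"`, `"REFLECTANCE"`,
#'   `"OTHER"`.
#' @return object of class `intensity_image`.
#' @export
intensity_image <- function(pixels, pixel_size_um, channel_label = "OTHER") {
  stop_if(!is.matrix(pixels) || !is.numeric(pixels),
          "pixels must be a numeric matrix")
  stop_if(nrow(pixels) < 8L || ncol(pixels) < 8L,
          fmt("image must be at least 8 x 8, got %d x %d",
              nrow(pixels), ncol(pixels)))
  stop_if(any(!is.finite(pixels)), "image contains non-finite values")
  stop_if(!is_scalar_num(pixel_size_um) || pixel_size_um <= 0,
          "pixel_size_um must be a positive number")
  channel_label <- match.arg(channel_label, CHANNEL_LABELS)
  structure(list(pixels = pixels, pixel_size_um = pixel_size_um,
                 channel_label = channel_label),
            class = "intensity_image")
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(fmt("<intensity_image> %d x %d px, %.4g um/px, channel %s, range [%.4g, %.4g]\n",
          nrow(x$pixels), ncol(x$pixels), x$pixel_size_um, x$channel_label,
          min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.intensity_image <- function(x) dim(x$pixels)

sidecar_path_for <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a single-channel grayscale TIFF
#'
#' Integer-valued images in `[0, 255]` / `[0, 65535]` are written as
#' uint8/uint16 (bit-exact round trip). Other images are written as 32-bit
#' float scaled by a power of two recorded in a JSON sidecar next to the
#' TIFF, so the round trip is exact in binary floating point.
#'
#' @param image an [intensity_image].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stop_if(!inherits(image, "intensity_image"), "image must be an intensity_image")
  m <- image$pixels
  meta <- list(pixel_size_um = image$pixel_size_um,
               channel_label = image$channel_label)
  integral <- all(m == round(m)) && min(m) >= 0
  if (integral && max(m) <= 255) {
    tiff::writeTIFF(m / 255, path, bits.per.sample = 8L, compression = "none")
  } else if (integral && max(m) <= 65535) {
    tiff::writeTIFF(m / 65535, path, bits.per.sample = 16L, compression = "none")
  } else {
    offset <- min(0, min(m))
    scale <- intensity_scale_for(m - offset)
    meta$intensity_scale <- scale
    meta$intensity_offset <- offset
    tiff::writeTIFF((m - offset) / scale, path,
                    bits.per.sample = 32L, compression = "none", reduce = FALSE)
  }
  jsonlite::write_json(meta, sidecar_path_for(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# smallest power of two >= max absolute intensity (at least 1); negative
# excursions from additive noise are shifted into [0,1] by the same scale
intensity_scale_for <- function(m) {
  mx <- max(abs(range(m)), 1)
  2^ceiling(log2(mx))
}

#' Read a single-channel grayscale TIFF
#'
#' Integer pixel types are converted to real values without rescaling.
#' Multi-channel (colour) input is rejected. A JSON sidecar written by
#' [write_image()] supplies pixel size, channel label and float scale;
#' arguments override sidecar values.
#'
#' @param path TIFF path.
#' @param pixel_size_um pixel size in micrometres; required when no sidecar
#'   is present.
#' @param channel_label channel label; defaults to sidecar value or "OTHER".
#' @return an [intensity_image].
#' @export
read_image <- function(path, pixel_size_um = NULL, channel_label = NULL) {
  stop_if(!file.exists(path), fmt("no such file: %s", path))
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  stop_if(length(pages) != 1L,
          fmt("expected single-page TIFF, got %d pages: %s", length(pages), path))
  img <- pages[[1L]]
  stop_if(length(dim(img)) == 3L,
          fmt("expected single-channel grayscale TIFF, got %d samples per pixel: %s",
              dim(img)[3L], path))
  info <- attributes(img)
  meta <- list()
  sc <- sidecar_path_for(path)
  if (file.exists(sc)) meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  is_uint <- identical(info$sample.format, "uint") ||
    (is.null(info$sample.format) &&
       isTRUE(info$bits.per.sample %in% c(8L, 16L)))
  if (is_uint) {
    img <- tiff::readTIFF(path, as.is = TRUE)  # raw integer counts
    m <- matrix(as.numeric(img), nrow(img), ncol(img))
  } else {
    scale <- meta$intensity_scale %||% 1
    offset <- meta$intensity_offset %||% 0
    m <- matrix(as.numeric(img) * scale + offset, nrow(img), ncol(img))
  }
  psz <- pixel_size_um %||% meta$pixel_size_um
  stop_if(is.null(psz), "pixel_size_um is required (not stored in this TIFF)")
  lab <- channel_label %||% meta$channel_label %||% "OTHER"
  intensity_image(m, psz, lab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- wavenumber axis --------------------------------------------------------

#' Uniform wavenumber axis
#'
#' The channel count is `floor((stop - start) / step) + 1`; the hyperspectral
#' acquisitions this models cover 2825-3075 cm-1 at 5 cm-1 steps (51 frames).
#'
#' @param start_cm1,stop_cm1 axis limits in cm-1 (`start < stop`).
#' @param step_cm1 channel spacing in cm-1 (> 0).
#' @return object of class `wavenumber_axis`.
#' @export
wavenumber_axis <- function(start_cm1, stop_cm1, step_cm1) {
  stop_if(!is_scalar_num(start_cm1) || !is_scalar_num(stop_cm1) ||
            !is_scalar_num(step_cm1), "axis parameters must be numbers")
  stop_if(step_cm1 <= 0, "step_cm1 must be positive")
  stop_if(start_cm1 >= stop_cm1, "start_cm1 must be below stop_cm1")
  structure(list(start_cm1 = as.numeric(start_cm1),
                 stop_cm1 = as.numeric(stop_cm1),
                 step_cm1 = as.numeric(step_cm1)),
            class = "wavenumber_axis")
}

#' @export
print.wavenumber_axis <- function(x, ...) {
  cat(fmt("<wavenumber_axis> %g to %g cm-1, step %g (%d channels)\n",
          x$start_cm1, x$stop_cm1, x$step_cm1, n_channels(x)))
  invisible(x)
}

#' Number of channels on a wavenumber axis
#' @param axis a [wavenumber_axis].
#' @export
n_channels <- function(axis) {
  as.integer(floor((axis$stop_cm1 - axis$start_cm1) / axis$step_cm1 + 1e-9)) + 1L
}

#' Channel wavenumbers of an axis
#' @param axis a [wavenumber_axis].
#' @return strictly ascending numeric vector, `start + (k-1) * step`.
#' @export
axis_values <- function(axis) {
  axis$start_cm1 + (seq_len(n_channels(axis)) - 1L) * axis$step_cm1
}

# ---- hyperspectral cube -----------------------------------------------------

#' Hyperspectral data cube
#'
#' A (row, col, channel) array in which every x-y pixel carries a vibrational
#' spectrum on a shared [wavenumber_axis].
#'
#' @param data 3-D numeric array; third dimension must match the axis
#'   channel count.
#' @param axis a [wavenumber_axis].
#' @param pixel_size_um physical pixel size in micrometres.
#' @return object of class `hyperspectral_cube`.
#' @export
hyperspectral_cube <- function(data, axis, pixel_size_um) {
  stop_if(!is.array(data) || length(dim(data)) != 3L,
          "data must be a 3-D array (row, col, channel)")
  stop_if(!inherits(axis, "wavenumber_axis"), "axis must be a wavenumber_axis")
  nc <- n_channels(axis)
  stop_if(dim(data)[3L] != nc,
          fmt("channel dimension (%d) does not match axis channel count (%d)",
              dim(data)[3L], nc))
  stop_if(any(!is.finite(data)), "cube contains non-finite values")
  stop_if(!is_scalar_num(pixel_size_um) || pixel_size_um <= 0,
          "pixel_size_um must be a positive number")
  structure(list(data = data, axis = axis, pixel_size_um = pixel_size_um),
            class = "hyperspectral_cube")
}

#' @export
print.hyperspectral_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(fmt("<hyperspectral_cube> %d x %d px, %d channels (%g-%g cm-1), %.4g um/px\n",
          d[1L], d[2L], d[3L], x$axis$start_cm1, x$axis$stop_cm1, x$pixel_size_um))
  invisible(x)
}

#' @export
dim.hyperspectral_cube <- function(x) dim(x$data)

#' Write a hyperspectral cube as multi-page TIFF plus JSON sidecar
#'
#' One float32 page per wavenumber, ascending; the sidecar records
#' `start_cm1`, `stop_cm1`, `step_cm1`, `pixel_size_um` and the power-of-two
#' `intensity_scale` applied before storage.
#'
#' @param cube a [hyperspectral_cube].
#' @param path output TIFF path.
#' @param sidecar_path JSON sidecar path (default: TIFF path with `.json`).
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, sidecar_path = sidecar_path_for(path)) {
  stop_if(!inherits(cube, "hyperspectral_cube"), "cube must be a hyperspectral_cube")
  offset <- min(0, min(cube$data))
  scale <- intensity_scale_for(cube$data - offset)
  pages <- lapply(seq_len(dim(cube$data)[3L]),
                  function(k) (cube$data[, , k] - offset) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(
    list(start_cm1 = cube$axis$start_cm1, stop_cm1 = cube$axis$stop_cm1,
         step_cm1 = cube$axis$step_cm1, pixel_size_um = cube$pixel_size_um,
         intensity_scale = scale, intensity_offset = offset),
    sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a hyperspectral cube from multi-page TIFF plus JSON sidecar
#'
#' Page `k` maps to wavenumber `start + (k-1) * step`. The page count must
#' equal the axis channel count or the read is rejected with both counts.
#'
#' @param path multi-page TIFF path.
#' @param sidecar_path JSON sidecar path (default: TIFF path with `.json`).
#' @return a [hyperspectral_cube].
#' @export
read_cube <- function(path, sidecar_path = sidecar_path_for(path)) {
  stop_if(!file.exists(path), fmt("no such file: %s", path))
  stop_if(!file.exists(sidecar_path), fmt("no such sidecar: %s", sidecar_path))
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (f in c("start_cm1", "stop_cm1", "step_cm1", "pixel_size_um"))
    stop_if(is.null(meta[[f]]), fmt("sidecar is missing field '%s'", f))
  axis <- wavenumber_axis(meta$start_cm1, meta$stop_cm1, meta$step_cm1)
  pages <- tiff::readTIFF(path, all = TRUE)
  nc <- n_channels(axis)
  stop_if(length(pages) != nc,
          fmt("page count (%d) does not match axis channel count (%d)",
              length(pages), nc))
  scale <- meta$intensity_scale %||% 1
  offset <- meta$intensity_offset %||% 0
  d <- dim(pages[[1L]])
  stop_if(length(d) != 2L, "cube pages must be single-channel grayscale")
  arr <- array(0, c(d[1L], d[2L], nc))
  for (k in seq_len(nc)) arr[, , k] <- pages[[k]] * scale + offset
  hyperspectral_cube(arr, axis, meta$pixel_size_um)
}

# ---- spectra ----------------------------------------------------------------

#' Intensity spectrum
#'
#' @param wavenumbers_cm1 strictly ascending numeric vector.
#' @param intensities finite numeric vector of equal length.
#' @param label free-text label.
#' @return object of class `spectrum`.
#' @export
spectrum <- function(wavenumbers_cm1, intensities, label = "") {
  stop_if(length(wavenumbers_cm1) != length(intensities),
          "wavenumbers and intensities must have equal length")
  stop_if(any(diff(wavenumbers_cm1) <= 0),
          "wavenumbers must be strictly ascending")
  stop_if(any(!is.finite(intensities)), "intensities must be finite")
  structure(list(wavenumbers_cm1 = as.numeric(wavenumbers_cm1),
                 intensities = as.numeric(intensities),
                 label = as.character(label)),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(fmt("<spectrum> '%s': %d points, %g-%g cm-1, max %.4g\n", x$label,
          length(x$intensities), min(x$wavenumbers_cm1), max(x$wavenumbers_cm1),
          max(x$intensities)))
  invisible(x)
}

#' Write a spectrum as two-column CSV
#'
#' Dialect: header `wavenumber_cm1,intensity`, comma separated, `.` decimal.
#' @param sp a [spectrum].
#' @param path output CSV path.
#' @export
write_spectrum <- function(sp, path) {
  stop_if(!inherits(sp, "spectrum"), "sp must be a spectrum")
  utils::write.csv(
    data.frame(wavenumber_cm1 = sp$wavenumbers_cm1, intensity = sp$intensities),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spectrum from two-column CSV
#' @param path CSV path with header `wavenumber_cm1,intensity`.
#' @param label label for the spectrum (default: file name).
#' @export
read_spectrum <- function(path, label = tools::file_path_sans_ext(basename(path))) {
  stop_if(!file.exists(path), fmt("no such file: %s", path))
  d <- utils::read.csv(path)
  stop_if(!all(c("wavenumber_cm1", "intensity") %in% names(d)),
          fmt("expected columns wavenumber_cm1,intensity in %s", path))
  spectrum(d$wavenumber_cm1, d$intensity, label)
}

# ---- regions of interest ----------------------------------------------------

#' Regions of interest
#'
#' Constructors for the ROI shapes used to extract spectra: a disk, an
#' axis-aligned ellipse, a polygon, or an explicit boolean mask. All resolve
#' to pixel sets via [roi_pixels()].
#'
#' @param center numeric (row, col) centre.
#' @param radius disk radius in pixels.
#' @param radii (row, col) semi-axes in pixels.
#' @param vertices n x 2 matrix of (row, col) polygon vertices.
#' @param mask logical matrix.
#' @name roi
NULL

#' @rdname roi
#' @export
roi_disk <- function(center, radius) {
  stop_if(length(center) != 2L || !is.numeric(center), "center must be (row, col)")
  stop_if(!is_scalar_num(radius) || radius < 0, "radius must be non-negative")
  structure(list(shape = "DISK", center = center, radius = radius), class = "roi")
}

#' @rdname roi
#' @export
roi_ellipse <- function(center, radii) {
  stop_if(length(center) != 2L || length(radii) != 2L, "center and radii must be (row, col)")
  stop_if(any(radii <= 0), "radii must be positive")
  structure(list(shape = "ELLIPSE", center = center, radii = radii), class = "roi")
}

#' @rdname roi
#' @export
roi_polygon <- function(vertices) {
  vertices <- as_pixel_matrix(vertices)
  stop_if(nrow(vertices) < 3L, "polygon needs at least 3 vertices")
  structure(list(shape = "POLYGON", vertices = vertices), class = "roi")
}

#' @rdname roi
#' @export
roi_mask <- function(mask) {
  stop_if(!is.matrix(mask) || !is.logical(mask), "mask must be a logical matrix")
  structure(list(shape = "MASK", mask = mask), class = "roi")
}

#' Resolve an ROI to its pixel set
#'
#' A disk of radius r contains exactly the pixels whose centres lie within
#' Euclidean distance r of the ROI centre; the ellipse analogously. Polygon
#' membership uses pixel centres. The resolution is deterministic; empty or
#' out-of-bounds ROIs are rejected.
#'
#' @param roi an ROI from [roi_disk()], [roi_ellipse()], [roi_polygon()] or
#'   [roi_mask()].
#' @param image_shape integer (rows, cols) of the target image.
#' @return integer matrix with columns `row`, `col`, ordered column-major.
#' @export
roi_pixels <- function(roi, image_shape) {
  stop_if(!inherits(roi, "roi"), "roi must be created by an roi_* constructor")
  stop_if(length(image_shape) != 2L, "image_shape must be (rows, cols)")
  nr <- image_shape[1L]; nc <- image_shape[2L]
  px <- switch(roi$shape,
    DISK = {
      g <- expand.grid(row = seq_len(nr), col = seq_len(nc))
      keep <- (g$row - roi$center[1L])^2 + (g$col - roi$center[2L])^2 <=
        roi$radius^2 + 1e-12
      as.matrix(g[keep, , drop = FALSE])
    },
    ELLIPSE = {
      g <- expand.grid(row = seq_len(nr), col = seq_len(nc))
      keep <- ((g$row - roi$center[1L]) / roi$radii[1L])^2 +
        ((g$col - roi$center[2L]) / roi$radii[2L])^2 <= 1 + 1e-12
      as.matrix(g[keep, , drop = FALSE])
    },
    POLYGON = {
      v <- roi$vertices
      stop_if(min(v) < 0.5 || max(v[, 1L]) > nr + 0.5 || max(v[, 2L]) > nc + 0.5,
              "polygon extends outside the image bounds")
      g <- expand.grid(row = seq_len(nr), col = seq_len(nc))
      keep <- pracma::inpolygon(g$row, g$col, v[, 1L], v[, 2L],
                                boundary = TRUE)
      as.matrix(g[keep, , drop = FALSE])
    },
    MASK = {
      stop_if(!all(dim(roi$mask) == c(nr, nc)),
              fmt("mask shape %d x %d does not match image shape %d x %d",
                  nrow(roi$mask), ncol(roi$mask), nr, nc))
      which(roi$mask, arr.ind = TRUE)
    })
  stop_if(nrow(px) == 0L, "ROI resolves to an empty pixel set")
  stop_if(min(px) < 1L || max(px[, 1L]) > nr || max(px[, 2L]) > nc,
          "ROI extends outside the image bounds")
  colnames(px) <- c("row", "col")
  storage.mode(px) <- "integer"
  px
}
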