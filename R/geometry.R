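# Planar geometry for needle objects: Feret diameter, minimum-area oriented
# bounding rectangles and convex rectangle intersection. Coordinates are
# (row, col) pixel centres, 1-based.

#' Maximum Feret diameter and orientation of a pixel set
#'
#' Length is the largest pairwise distance between pixel centres plus one
#' pixel extent along the maximizing chord, converted to micrometres.
#' For straight needles this equals the rendered needle length to within the
#' rasterization error of the mask. A single pixel has length one pixel and
#' orientation 0 by convention.
#'
#' @param pixels integer matrix with two columns (row, col), one row per pixel.
#' @param pixel_size_um physical pixel size in micrometres.
#' @return list with `length_um` and `orientation_deg` (in `[0, 180)`,
#'   measured from the row axis towards increasing column).
#' @export
measure_length <- function(pixels, pixel_size_um) {
  pixels <- as_pixel_matrix(pixels)
  stop_if(!is_scalar_num(pixel_size_um) || pixel_size_um <= 0,
          "pixel_size_um must be a positive number")
  if (nrow(pixels) == 1L)
    return(list(length_um = pixel_size_um, orientation_deg = 0))
  hp <- hull_points(pixels)
  d <- as.matrix(stats::dist(hp))
  idx <- which(d == max(d), arr.ind = TRUE)[1L, ]
  p <- hp[idx[1L], ]; q <- hp[idx[2L], ]
  len_px <- d[idx[1L], idx[2L]] + 1
  ang <- atan2(q[2L] - p[2L], q[1L] - p[1L]) * 180 / pi
  ang <- ang %% 180
  list(length_um = len_px * pixel_size_um, orientation_deg = ang)
}

as_pixel_matrix <- function(pixels) {
  if (is.data.frame(pixels)) pixels <- as.matrix(pixels)
  stop_if(!is.matrix(pixels) || ncol(pixels) != 2L || nrow(pixels) < 1L,
          "pixels must be an n x 2 matrix of (row, col)")
  storage.mode(pixels) <- "double"
  pixels
}

# Convex hull vertices of a point set (degenerate sets handled).
hull_points <- function(pts) {
  if (nrow(pts) <= 2L) return(pts)
  h <- grDevices::chull(pts[, 2L], pts[, 1L])
  pts[h, , drop = FALSE]
}

#' Minimum-area oriented bounding rectangle of a pixel set
#'
#' Rotating-calipers search over convex-hull edge directions. Extents get one
#' pixel added per dimension so that a 1-pixel-wide segment has unit width.
#'
#' @param pixels n x 2 matrix of (row, col) pixel centres.
#' @return list: `center`, `angle_deg` (long-axis direction in `[0,180)`),
#'   `length_px`, `width_px`, `area_px2`, and `corners` (4 x 2 matrix).
#' @keywords internal
min_area_rect <- function(pixels) {
  pts <- as_pixel_matrix(pixels)
  hp <- hull_points(pts)
  if (nrow(hp) == 1L) {
    c0 <- hp[1L, ]
    corners <- cbind(c0[1L] + c(-0.5, -0.5, 0.5, 0.5),
                     c0[2L] + c(-0.5, 0.5, 0.5, -0.5))
    return(list(center = c0, angle_deg = 0, length_px = 1, width_px = 1,
                area_px2 = 1, corners = corners))
  }
  best <- NULL
  n <- nrow(hp)
  for (i in seq_len(max(n - 1L, 1L))) {
    j <- if (i == n) 1L else i + 1L
    e <- hp[j, ] - hp[i, ]
    L <- sqrt(sum(e^2))
    if (L < 1e-12) next
    e <- e / L
    nv <- c(-e[2L], e[1L])
    pu <- hp %*% e
    pv <- hp %*% nv
    du <- max(pu) - min(pu) + 1
    dv <- max(pv) - min(pv) + 1
    area <- du * dv
    if (is.null(best) || area < best$area_px2 - 1e-12) {
      ctr_uv <- c((max(pu) + min(pu)) / 2, (max(pv) + min(pv)) / 2)
      center <- ctr_uv[1L] * e + ctr_uv[2L] * nv
      if (du >= dv) { axis <- e; Lpx <- du; Wpx <- dv } else {
        axis <- nv; Lpx <- dv; Wpx <- du
      }
      half_u <- (Lpx / 2) * axis
      half_v <- (Wpx / 2) * c(-axis[2L], axis[1L])
      corners <- rbind(center + half_u + half_v, center + half_u - half_v,
                       center - half_u - half_v, center - half_u + half_v)
      best <- list(center = center,
                   angle_deg = (atan2(axis[2L], axis[1L]) * 180 / pi) %% 180,
                   length_px = Lpx, width_px = Wpx, area_px2 = area,
                   corners = corners)
    }
  }
  best
}

# Area of the intersection of two convex polygons (Sutherland-Hodgman
# clipping followed by the shoelace formula). Vertices in (row, col).
convex_intersection_area <- function(poly_a, poly_b) {
  subject <- poly_a
  nb <- nrow(poly_b)
  # ensure counter-clockwise orientation of the clip polygon
  if (shoelace_area_signed(poly_b) < 0) poly_b <- poly_b[nb:1, , drop = FALSE]
  for (i in seq_len(nb)) {
    if (is.null(subject) || nrow(subject) == 0L) return(0)
    a <- poly_b[i, ]
    b <- poly_b[if (i == nb) 1L else i + 1L, ]
    subject <- clip_halfplane(subject, a, b)
  }
  if (is.null(subject) || nrow(subject) < 3L) return(0)
  abs(shoelace_area_signed(subject))
}

shoelace_area_signed <- function(p) {
  n <- nrow(p)
  j <- c(2:n, 1L)
  sum(p[, 1L] * p[j, 2L] - p[j, 1L] * p[, 2L]) / 2
}

clip_halfplane <- function(poly, a, b) {
  n <- nrow(poly)
  side <- function(p) (b[1L] - a[1L]) * (p[2L] - a[2L]) -
    (b[2L] - a[2L]) * (p[1L] - a[1L])
  out <- matrix(numeric(0), 0L, 2L)
  for (i in seq_len(n)) {
    p <- poly[i, ]
    q <- poly[if (i == n) 1L else i + 1L, ]
    sp <- side(p); sq <- side(q)
    if (sp >= -1e-12) out <- rbind(out, p)
    if ((sp > 1e-12 && sq < -1e-12) || (sp < -1e-12 && sq > 1e-12)) {
      t <- sp / (sp - sq)
      out <- rbind(out, p + t * (q - p))
    }
  }
  out
}
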