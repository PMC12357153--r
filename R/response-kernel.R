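# The 2-D super-Gaussian spatial response function and per-(pixel, polygon)
# weights for the physics-based (PGO) and area-weighted (AWO) schemes.
#
# S(x, y) = exp(-(|x/w_x|^n + |y/w_y|^m)) with w = FWHM / (2 (ln 2)^{1/k});
# the natural logarithm is forced by S(+-FWHM/2, 0) = 1/2. A push-broom
# imager is well described by n = 2 along-track and m = 4 across-track.

#' Super-Gaussian width parameter from a full width at half maximum
#'
#' Returns `fwhm / (2 * (log(2))^(1/exponent))`, the width `w` at which the
#' 1-D factor `exp(-|x/w|^k)` has dropped to `exp(-1)`; by construction the
#' factor equals 1/2 at `x = fwhm/2`.
#'
#' @param fwhm Full width at half maximum, km (> 0).
#' @param exponent Super-Gaussian exponent (> 0); 2 gives an ordinary
#'   Gaussian, large values approach a boxcar of width `fwhm`.
#' @return Width in km.
#' @export
#' @examples
#' width_from_fwhm(2, 2)   # 1/sqrt(log(2)) = 1.2011
width_from_fwhm <- function(fwhm, exponent) {
  if (any(fwhm <= 0) || any(exponent <= 0)) {
    stop("width_from_fwhm: fwhm and exponent must be positive")
  }
  fwhm / (2 * log(2)^(1 / exponent))
}

#' Construct a super-Gaussian spatial response kernel
#'
#' @param fwhm_x,fwhm_y Full widths at half maximum along- and across-track,
#'   km.
#' @param n,m Super-Gaussian exponents along- and across-track (defaults 2
#'   and 4, the push-broom imager shape).
#' @return An object of class `response_kernel` with fields `fwhm_x`,
#'   `fwhm_y`, `n`, `m`, `w_x`, `w_y`.
#' @export
response_kernel <- function(fwhm_x, fwhm_y, n = 2, m = 4) {
  structure(list(
    fwhm_x = fwhm_x, fwhm_y = fwhm_y, n = n, m = m,
    w_x = width_from_fwhm(fwhm_x, n), w_y = width_from_fwhm(fwhm_y, m)
  ), class = "response_kernel")
}

#' Evaluate the spatial response function
#'
#' @param kernel A [response_kernel()].
#' @param x,y Along- and across-track distances from the footprint centre,
#'   km (vectorised).
#' @return Sensitivities in (0, 1]; 1 at the centre, 1/2 at half maximum.
#' @export
evaluate_response <- function(kernel, x, y) {
  exp(-(abs(x / kernel$w_x)^kernel$n + abs(y / kernel$w_y)^kernel$m))
}

#' Rasterize a polygon over its bounding box
#'
#' Lays a `resolution` x `resolution` grid over the lon/lat bounding box of
#' each polygon part and computes, for every cell, the exact area of the
#' cell covered by the polygon (convex clipping of the cell rectangle
#' against the polygon rings; holes subtract). Cells with zero coverage are
#' dropped. Areas are km^2 at the part centroid latitude; multi-part
#' geometries are rasterized per part and concatenated.
#'
#' @param geometry A polygon geometry (matrix ring, list of rings, or list
#'   of parts, lon/lat).
#' @param resolution Cells per side of the raster (default 10).
#' @return A list with `lon`, `lat` (covered cell centres), `area_km2`
#'   (covered area per cell) and `n_inside` (number of covered cells).
#' @export
rasterize_polygon <- function(geometry, resolution = 10) {
  g <- as_geometry(geometry)
  if (resolution < 2) stop("rasterize_polygon: resolution must be >= 2")
  lon <- numeric(0); lat <- numeric(0); area <- numeric(0)
  for (part in g) {
    bb <- geometry_bbox(list(part))
    dx <- (bb[["lon_max"]] - bb[["lon_min"]]) / resolution
    dy <- (bb[["lat_max"]] - bb[["lat_min"]]) / resolution
    if (dx <= 0 || dy <= 0) next
    lat0 <- ring_centroid(part[[1]])[2]
    # planar degree-space clipping; areas scale affinely to km^2
    deg2km2 <- km_per_degree()^2 * cos(lat0 * pi / 180)
    rings <- lapply(part, ensure_ccw)
    for (iy in seq_len(resolution)) {
      y0 <- bb[["lat_min"]] + (iy - 1) * dy
      for (ix in seq_len(resolution)) {
        x0 <- bb[["lon_min"]] + (ix - 1) * dx
        cell <- rect_ring(x0, y0, x0 + dx, y0 + dy)
        a <- 0
        for (r in seq_along(rings)) {
          cl <- clip_ring_convex(rings[[r]], cell)
          if (nrow(cl) >= 3) {
            ra <- abs(ring_area_signed(cl))
            a <- a + if (r == 1L) ra else -ra
          }
        }
        if (a > 0) {
          lon <- c(lon, x0 + dx / 2); lat <- c(lat, y0 + dy / 2)
          area <- c(area, a * deg2km2)
        }
      }
    }
  }
  list(lon = lon, lat = lat, area_km2 = area, n_inside = length(lon))
}

#' Physics-based (super-Gaussian) weight of a footprint for a polygon
#'
#' The polygon is rasterized over its bounding box; the response function is
#' evaluated at every inside cell centre in the pixel-local frame and summed
#' with cell areas as quadrature weights, approximating the integral of
#' S(x, y) over the polygon (km^2). If no raster cell centre falls inside
#' (degenerate slivers), the fallback is S at the polygon centroid times the
#' polygon area.
#'
#' @param pixel One observation row (corner convention enforced).
#' @param kernel The pixel's [response_kernel()].
#' @param frame The pixel's [local_frame()].
#' @param polygon A one-row polygon tibble with `geometry` (and optionally
#'   `area_km2`), or a raw geometry.
#' @param resolution Raster cells per side (default 10).
#' @return Non-negative weight, km^2.
#' @export
pgo_weight <- function(pixel, kernel, frame, polygon, resolution = 10) {
  g <- if (is.data.frame(polygon)) polygon$geometry[[1]] else polygon
  ras <- rasterize_polygon(g, resolution)
  if (ras$n_inside == 0) {
    ct <- geometry_centroid(g)
    xy <- pixel_coords(frame, ct[1], ct[2])
    return(evaluate_response(kernel, xy[, 1], xy[, 2]) * geometry_area_km2(g))
  }
  xy <- pixel_coords(frame, ras$lon, ras$lat)
  sum(evaluate_response(kernel, xy[, 1], xy[, 2]) * ras$area_km2)
}

#' Area-overlap weight of a footprint for a polygon
#'
#' The area of the geometric intersection between the footprint
#' quadrilateral and the polygon, computed by convex clipping in a local
#' equirectangular frame at the pair's mean latitude.
#'
#' @inheritParams pgo_weight
#' @return Overlap area, km^2 (zero when disjoint).
#' @export
awo_weight <- function(pixel, polygon) {
  g <- if (is.data.frame(polygon)) polygon$geometry[[1]] else polygon
  quad <- corner_mat(pixel)
  geometry_quad_overlap_km2(g, quad)
}
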