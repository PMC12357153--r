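# Pixel-local coordinate frames for push-broom swath footprints.
#
# Each Level-2 observation is a quadrilateral footprint given by its centre
# and four corners in lon/lat. The spatial response function is defined in a
# pixel-local frame whose axes are the along-track (x) and across-track (y)
# directions; this file builds that frame and converts lon/lat points into
# (x, y) kilometres.
#
# Corner convention (enforced by `normalize_corners()`, emitted natively by
# the synthetic generator): corners are ordered so that, in the pixel's own
# frame, corner 1 sits in the (-along, -across) quadrant, corners 1-2 form
# the trailing across-track edge and corners 3-4 the leading across-track
# edge. The across axis is the +90 degree counterclockwise rotation of the
# along axis.

corner_mat <- function(pixel) {
  cbind(c(pixel$lon0, pixel$lon1, pixel$lon2, pixel$lon3),
        c(pixel$lat0, pixel$lat1, pixel$lat2, pixel$lat3))
}

#' Build the local tangent-plane frame of one footprint
#'
#' Constructs the pixel-local coordinate frame: an equirectangular tangent
#' plane at the pixel centre whose x axis is the along-track direction (from
#' the midpoint of the trailing corner edge to the midpoint of the leading
#' corner edge) and whose y axis is its +90 degree counterclockwise
#' rotation (across-track).
#'
#' @param pixel A one-row data frame (or list) with `lon`, `lat` and corner
#'   columns `lon0..lon3`, `lat0..lat3` in the package corner convention
#'   (see [normalize_corners()]).
#' @return An object of class `local_frame`: a list with `origin` (lon/lat),
#'   `east_scale` and `north_scale` (km per degree), and unit vectors
#'   `along` and `across` in the (east, north) km basis.
#' @export
#' @examples
#' px <- tibble::tibble(lon = 0, lat = 0,
#'   lon0 = -0.25, lat0 = -0.5, lon1 = 0.25, lat1 = -0.5,
#'   lon2 = 0.25, lat2 = 0.5, lon3 = -0.25, lat3 = 0.5)
#' local_frame(normalize_corners(px))
local_frame <- function(pixel) {
  if (abs(pixel$lat) >= 85) {
    stop("local_frame: polar pixels (|lat| >= 85 deg) are not supported")
  }
  corners <- corner_mat(pixel)
  nsc <- km_per_degree()
  esc <- nsc * cos(pixel$lat * pi / 180)
  km <- cbind((corners[, 1] - pixel$lon) * esc, (corners[, 2] - pixel$lat) * nsc)
  edge_len <- sqrt(rowSums((km - km[c(2, 3, 4, 1), ])^2))
  if (any(edge_len < 1e-9)) {
    stop("local_frame: degenerate footprint (zero-length edge)")
  }
  mid01 <- (km[1, ] + km[2, ]) / 2
  mid23 <- (km[3, ] + km[4, ]) / 2
  v <- mid23 - mid01
  len <- sqrt(sum(v^2))
  if (len < 1e-9) stop("local_frame: degenerate footprint (collapsed edges)")
  along <- v / len
  structure(list(
    origin = c(lon = unname(pixel$lon), lat = unname(pixel$lat)),
    east_scale = esc, north_scale = nsc,
    along = along, across = c(-along[2], along[1])
  ), class = "local_frame")
}

#' Convert lon/lat points to pixel-local (x, y) kilometres
#'
#' @param frame A [local_frame()].
#' @param lon,lat Numeric vectors of point coordinates (degrees).
#' @return A two-column matrix with along-track `x` and across-track `y`
#'   distances in km from the pixel centre.
#' @export
pixel_coords <- function(frame, lon, lat) {
  de <- (lon - frame$origin[["lon"]]) * frame$east_scale
  dn <- (lat - frame$origin[["lat"]]) * frame$north_scale
  cbind(x = de * frame$along[1] + dn * frame$along[2],
        y = de * frame$across[1] + dn * frame$across[2])
}

#' Footprint full widths at half maximum from the corner geometry
#'
#' The along-track FWHM is the distance between the midpoints of the two
#' across-track (trailing and leading) corner edges; the across-track FWHM
#' is the distance between the midpoints of the two along-track edges. These
#' corner-derived extents parameterise the super-Gaussian response.
#'
#' @inheritParams local_frame
#' @param frame The pixel's [local_frame()].
#' @return Named numeric vector `c(fwhm_x = , fwhm_y = )`, km.
#' @export
derive_fwhm <- function(pixel, frame) {
  corners <- corner_mat(pixel)
  km <- cbind((corners[, 1] - frame$origin[["lon"]]) * frame$east_scale,
              (corners[, 2] - frame$origin[["lat"]]) * frame$north_scale)
  fx <- sqrt(sum(((km[3, ] + km[4, ]) / 2 - (km[1, ] + km[2, ]) / 2)^2))
  fy <- sqrt(sum(((km[2, ] + km[3, ]) / 2 - (km[4, ] + km[1, ]) / 2)^2))
  if (fx <= 0 || fy <= 0) stop("derive_fwhm: non-positive footprint extent")
  c(fwhm_x = fx, fwhm_y = fy)
}

#' Normalise footprint corner order to the package convention
#'
#' Reorders the four corner columns of each observation so that corner 1
#' lies in the (-along, -across) quadrant of the pixel's own frame and
#' corners 1-2 / 3-4 are the trailing / leading across-track edges. All
#' readers apply this on ingest so downstream code can rely on corner roles.
#'
#' @param observations A data frame of pixel observations with `lon`, `lat`
#'   and `lon0..lon3`, `lat0..lat3` columns.
#' @return The same tibble with corner columns reordered per row.
#' @export
normalize_corners <- function(observations) {
  obs <- tibble::as_tibble(observations)
  loncols <- paste0("lon", 0:3); latcols <- paste0("lat", 0:3)
  for (i in seq_len(nrow(obs))) {
    cm <- cbind(as.numeric(unlist(obs[i, loncols])), as.numeric(unlist(obs[i, latcols])))
    ord <- canonical_corner_order(cm, obs$lon[i], obs$lat[i])
    obs[i, loncols] <- as.list(cm[ord, 1])
    obs[i, latcols] <- as.list(cm[ord, 2])
  }
  obs
}

# Find the cyclic/reflected corner order satisfying the convention: build
# the frame from each candidate ordering and keep the one whose corners fall
# in quadrants (-,-), (-,+), (+,+), (+,-) of (along, across).
canonical_corner_order <- function(corners, lon, lat) {
  nsc <- km_per_degree(); esc <- nsc * cos(lat * pi / 180)
  km <- cbind((corners[, 1] - lon) * esc, (corners[, 2] - lat) * nsc)
  ang <- atan2(km[, 2], km[, 1])
  ccw <- order(ang)
  candidates <- c(
    lapply(0:3, function(s) ccw[((seq_len(4) - 1 + s) %% 4) + 1]),
    lapply(0:3, function(s) rev(ccw)[((seq_len(4) - 1 + s) %% 4) + 1])
  )
  target <- matrix(c(-1, -1, -1, 1, 1, 1, 1, -1), ncol = 2, byrow = TRUE)
  best <- NULL; best_key <- c(-Inf, -Inf)
  for (ord in candidates) {
    k <- km[ord, , drop = FALSE]
    v <- (k[3, ] + k[4, ]) / 2 - (k[1, ] + k[2, ]) / 2
    len <- sqrt(sum(v^2))
    if (len < 1e-9) next
    along <- v / len; across <- c(-along[2], along[1])
    xy <- cbind(k %*% along, k %*% across)
    if (all(sign(xy) == target)) {
      # a centro-symmetric footprint admits two solutions (along and -along);
      # break the tie towards the north-, then east-pointing along axis
      key <- c(along[2], along[1])
      if (key[1] > best_key[1] ||
          (key[1] == best_key[1] && key[2] > best_key[2])) {
        best <- ord; best_key <- key
      }
    }
  }
  if (is.null(best)) {
    stop("canonical_corner_order: no corner ordering satisfies the ",
         "convention (degenerate or self-intersecting footprint?)")
  }
  best
}
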