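# Low-level planar geometry on lon/lat coordinates.
#
# All distances and areas use a local equirectangular approximation:
# 1 degree of latitude = `km_per_degree()` km, 1 degree of longitude =
# km_per_degree() * cos(latitude). At footprint scale (a few km) the error
# versus full geodesics is below 0.2% and cancels in weight ratios.
#
# Polygon geometry is stored as a list-column: each element is a list of
# parts (multipolygon support); each part is a list of rings (first ring
# exterior, later rings holes); each ring is an n x 2 matrix of lon/lat.

#' Kilometres per degree of latitude
#'
#' Mean-earth-radius circumference divided by 360, the scaling used for all
#' local tangent-plane conversions in the package.
#'
#' @return A single number, kilometres per degree (about 111.195).
#' @export
km_per_degree <- function() 111.19493

# signed shoelace area of one ring (planar units of the ring coordinates)
ring_area_signed <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(seq_len(nrow(ring))[-1L], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

# shoelace centroid of one ring; falls back to vertex mean for degenerate rings
ring_centroid <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(seq_len(nrow(ring))[-1L], 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-14) return(c(mean(x), mean(y)))
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

ensure_ccw <- function(ring) {
  if (ring_area_signed(ring) < 0) ring[rev(seq_len(nrow(ring))), , drop = FALSE] else ring
}

# Even-odd point-in-polygon over a list of rings, vectorised over points.
# Points exactly on a ring edge count as inside.
points_in_rings <- function(px, py, rings, eps = 1e-12) {
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  for (ring in rings) {
    n <- nrow(ring)
    xi <- ring[, 1]; yi <- ring[, 2]
    xj <- ring[c(n, seq_len(n - 1L)), 1]; yj <- ring[c(n, seq_len(n - 1L)), 2]
    for (k in seq_len(n)) {
      x1 <- xi[k]; y1 <- yi[k]; x2 <- xj[k]; y2 <- yj[k]
      crosses <- ((y1 > py) != (y2 > py))
      if (any(crosses)) {
        xint <- x1 + (py[crosses] - y1) * (x2 - x1) / (y2 - y1)
        hit <- px[crosses] < xint
        idx <- which(crosses)[hit]
        inside[idx] <- !inside[idx]
      }
      # boundary test: |cross| small and point within the segment's bbox
      dx <- x2 - x1; dy <- y2 - y1
      cr <- (px - x1) * dy - (py - y1) * dx
      seg <- abs(cr) <= eps * (abs(dx) + abs(dy) + 1) &
        px >= pmin(x1, x2) - eps & px <= pmax(x1, x2) + eps &
        py >= pmin(y1, y2) - eps & py <= pmax(y1, y2) + eps
      on_edge <- on_edge | seg
    }
  }
  inside | on_edge
}

# Sutherland-Hodgman: clip a subject ring by a convex CCW clip polygon.
# Both are n x 2 matrices in the same planar frame. Returns the clipped ring
# (possibly with zero rows).
clip_ring_convex <- function(ring, clip) {
  out <- ring
  nc <- nrow(clip)
  for (k in seq_len(nc)) {
    if (nrow(out) == 0) return(out)
    a <- clip[k, ]; b <- clip[if (k == nc) 1L else k + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    x <- out[, 1]; y <- out[, 2]
    side <- ex * (y - a[2]) - ey * (x - a[1])   # >= 0 means inside (left of edge)
    n <- nrow(out)
    prev <- c(n, seq_len(n - 1L))
    res_x <- numeric(0); res_y <- numeric(0)
    for (i in seq_len(n)) {
      p <- prev[i]
      cur_in <- side[i] >= 0; prev_in <- side[p] >= 0
      if (cur_in != prev_in) {
        t <- side[p] / (side[p] - side[i])
        res_x <- c(res_x, x[p] + t * (x[i] - x[p]))
        res_y <- c(res_y, y[p] + t * (y[i] - y[p]))
      }
      if (cur_in) {
        res_x <- c(res_x, x[i]); res_y <- c(res_y, y[i])
      }
    }
    out <- cbind(res_x, res_y, deparse.level = 0)
  }
  out
}

# --- geometry list-column helpers -------------------------------------------

# normalise a geometry specification to list(parts); each part list(rings)
as_geometry <- function(g) {
  if (is.matrix(g)) return(list(list(g)))
  if (is.list(g) && length(g) > 0 && is.matrix(g[[1]])) return(list(g))
  g
}

geometry_bbox <- function(g) {
  g <- as_geometry(g)
  pts <- do.call(rbind, unlist(g, recursive = FALSE))
  c(lon_min = min(pts[, 1]), lat_min = min(pts[, 2]),
    lon_max = max(pts[, 1]), lat_max = max(pts[, 2]))
}

# area in km^2 (equirectangular at each part's centroid latitude);
# holes subtract
geometry_area_km2 <- function(g) {
  g <- as_geometry(g)
  total <- 0
  for (part in g) {
    lat0 <- ring_centroid(part[[1]])[2]
    sx <- km_per_degree() * cos(lat0 * pi / 180)
    sy <- km_per_degree()
    for (i in seq_along(part)) {
      ring <- part[[i]]
      a <- abs(ring_area_signed(cbind(ring[, 1] * sx, ring[, 2] * sy)))
      total <- total + if (i == 1L) a else -a
    }
  }
  total
}

# area-weighted centroid in lon/lat (degree-space shoelace; adequate at
# polygon scale)
geometry_centroid <- function(g) {
  g <- as_geometry(g)
  cx <- 0; cy <- 0; aa <- 0
  for (part in g) {
    for (i in seq_along(part)) {
      ring <- part[[i]]
      a <- abs(ring_area_signed(ring)) * (if (i == 1L) 1 else -1)
      ct <- ring_centroid(ring)
      cx <- cx + a * ct[1]; cy <- cy + a * ct[2]; aa <- aa + a
    }
  }
  if (aa <= 0) {
    pts <- do.call(rbind, unlist(g, recursive = FALSE))
    return(c(mean(pts[, 1]), mean(pts[, 2])))
  }
  c(cx / aa, cy / aa)
}

# all rings of all parts, flattened (for even-odd inside tests)
geometry_rings <- function(g) unlist(as_geometry(g), recursive = FALSE)

# Area (km^2) of the intersection between a geometry and a convex
# quadrilateral given as a 4 x 2 lon/lat matrix. Clipping runs in a local
# km frame at `lat_ref` (defaults to the mean latitude of the two shapes).
geometry_quad_overlap_km2 <- function(g, quad, lat_ref = NULL) {
  g <- as_geometry(g)
  if (is.null(lat_ref)) {
    lat_ref <- (mean(quad[, 2]) + geometry_centroid(g)[2]) / 2
  }
  sx <- km_per_degree() * cos(lat_ref * pi / 180)
  sy <- km_per_degree()
  lon0 <- mean(quad[, 1]); lat0 <- mean(quad[, 2])
  to_km <- function(m) cbind((m[, 1] - lon0) * sx, (m[, 2] - lat0) * sy)
  clip <- ensure_ccw(to_km(quad))
  total <- 0
  for (part in g) {
    for (i in seq_along(part)) {
      cl <- clip_ring_convex(ensure_ccw(to_km(part[[i]])), clip)
      if (nrow(cl) >= 3) {
        a <- abs(ring_area_signed(cl))
        total <- total + if (i == 1L) a else -a
      }
    }
  }
  max(total, 0)
}

# axis-aligned rectangle ring helper (lon/lat)
rect_ring <- function(lon_min, lat_min, lon_max, lat_max) {
  cbind(c(lon_min, lon_max, lon_max, lon_min),
        c(lat_min, lat_min, lat_max, lat_max))
}
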