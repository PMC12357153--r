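# Shared fixture builders and independent oracles. Oracles deliberately use
# their own formulas (and pracma's point-in-polygon) rather than package
# internals.

KM_DEG <- swathover::km_per_degree()

# Build one footprint row from its centre, along/across extents (km) and
# ground-track azimuth (degrees from north), with corners emitted directly
# in the package convention: (-along, -across), (-along, +across),
# (+along, +across), (+along, -across).
make_pixel <- function(lon = 0, lat = 0, fwhm_x = 5.5, fwhm_y = 3.5,
                       azimuth = 0, value = 1, qa = 1,
                       date = as.Date("2021-06-01"), id = "px1") {
  corners_xy <- rbind(c(-fwhm_x / 2, -fwhm_y / 2), c(-fwhm_x / 2, fwhm_y / 2),
                      c(fwhm_x / 2, fwhm_y / 2), c(fwhm_x / 2, -fwhm_y / 2))
  pixel_from_xy(corners_xy, lon = lon, lat = lat, azimuth = azimuth,
                value = value, qa = qa, date = date, id = id)
}

# Arbitrary footprint from corner coordinates given in the pixel's own
# (along, across) km frame, already in convention order.
pixel_from_xy <- function(corners_xy, lon = 0, lat = 0, azimuth = 0,
                          value = 1, qa = 1, date = as.Date("2021-06-01"),
                          id = "px1") {
  az <- azimuth * pi / 180
  A <- c(sin(az), cos(az))            # along unit (east, north)
  X <- c(-A[2], A[1])                 # across unit (+90 deg CCW)
  km <- corners_xy %*% rbind(A, X)    # east/north km offsets
  esc <- KM_DEG * cos(lat * pi / 180)
  cl <- lon + km[, 1] / esc
  ct <- lat + km[, 2] / KM_DEG
  tibble::tibble(id = id, date = date, lon = lon, lat = lat,
                 lon0 = cl[1], lat0 = ct[1], lon1 = cl[2], lat1 = ct[2],
                 lon2 = cl[3], lat2 = ct[3], lon3 = cl[4], lat3 = ct[4],
                 value = value, qa = qa)
}

# Polygon tibble from one or more rings (matrices of lon/lat)
poly_tbl <- function(..., geoid = NULL) {
  rings <- list(...)
  if (is.null(geoid)) geoid <- paste0("P", seq_along(rings))
  tibble::tibble(
    geoid = geoid,
    geometry = lapply(rings, function(r) list(list(r)))
  )
}

# axis-aligned rectangle ring in lon/lat
rect_lonlat <- function(lon_min, lat_min, lon_max, lat_max) {
  cbind(c(lon_min, lon_max, lon_max, lon_min),
        c(lat_min, lat_min, lat_max, lat_max))
}

# a rectangle ring in km centred at (lon, lat), axis-aligned in lon/lat
rect_km <- function(cx_km, cy_km, w_km, h_km, lat0 = 0, lon0 = 0) {
  esc <- KM_DEG * cos(lat0 * pi / 180)
  rect_lonlat(lon0 + (cx_km - w_km / 2) / esc, lat0 + (cy_km - h_km / 2) / KM_DEG,
              lon0 + (cx_km + w_km / 2) / esc, lat0 + (cy_km + h_km / 2) / KM_DEG)
}

# seeded random convex polygon ring (lon/lat) of roughly `scale_km` extent
# centred at (cx_km, cy_km) km from (lon0, lat0)
random_convex_ring <- function(cx_km, cy_km, scale_km = 2, nv = 8, lat0 = 0,
                               lon0 = 0) {
  ang <- sort(stats::runif(nv, 0, 2 * pi))
  r <- stats::runif(nv, 0.3, 0.5) * scale_km
  xs <- cx_km + r * cos(ang)
  ys <- cy_km + r * sin(ang)
  hull <- grDevices::chull(xs, ys)
  esc <- KM_DEG * cos(lat0 * pi / 180)
  cbind(lon0 + xs[hull] / esc, lat0 + ys[hull] / KM_DEG)
}

# Independent brute-force quadrature of the super-Gaussian integral over a
# polygon: midpoint rule on an n x n grid over the ring bbox, inside test
# from pracma, S written out from its definition.
quadrature_pgo_oracle <- function(ring, pixel, n_exp = 2, m_exp = 4,
                                  n_grid = 400) {
  esc <- KM_DEG * cos(pixel$lat * pi / 180)
  # ring in km relative to the pixel centre (equirectangular at pixel lat)
  rx <- (ring[, 1] - pixel$lon) * esc
  ry <- (ring[, 2] - pixel$lat) * KM_DEG
  # footprint frame from corner midpoints
  cx <- (c(pixel$lon0, pixel$lon1, pixel$lon2, pixel$lon3) - pixel$lon) * esc
  cy <- (c(pixel$lat0, pixel$lat1, pixel$lat2, pixel$lat3) - pixel$lat) * KM_DEG
  v <- c(mean(cx[3:4]) - mean(cx[1:2]), mean(cy[3:4]) - mean(cy[1:2]))
  fwhm_x <- sqrt(sum(v^2)); A <- v / fwhm_x; X <- c(-A[2], A[1])
  fwhm_y <- sqrt((mean(cx[2:3]) - mean(cx[c(4, 1)]))^2 +
                 (mean(cy[2:3]) - mean(cy[c(4, 1)]))^2)
  wx <- fwhm_x / (2 * log(2)^(1 / n_exp))
  wy <- fwhm_y / (2 * log(2)^(1 / m_exp))
  gx <- seq(min(rx), max(rx), length.out = n_grid + 1)
  gy <- seq(min(ry), max(ry), length.out = n_grid + 1)
  mx <- (gx[-1] + gx[-length(gx)]) / 2
  my <- (gy[-1] + gy[-length(gy)]) / 2
  px <- rep(mx, times = n_grid); py <- rep(my, each = n_grid)
  keep <- pracma::inpolygon(px, py, rx, ry, boundary = TRUE)
  cell <- diff(gx)[1] * diff(gy)[1]
  x <- px[keep] * A[1] + py[keep] * A[2]
  y <- px[keep] * X[1] + py[keep] * X[2]
  sum(exp(-(abs(x / wx)^n_exp + abs(y / wy)^m_exp))) * cell
}

# Independent Monte-Carlo polygon/quadrilateral overlap area (km^2)
mc_overlap_oracle <- function(ring, pixel, n_pts = 2e5) {
  esc <- KM_DEG * cos(pixel$lat * pi / 180)
  rx <- (ring[, 1] - pixel$lon) * esc
  ry <- (ring[, 2] - pixel$lat) * KM_DEG
  qx <- (c(pixel$lon0, pixel$lon1, pixel$lon2, pixel$lon3) - pixel$lon) * esc
  qy <- (c(pixel$lat0, pixel$lat1, pixel$lat2, pixel$lat3) - pixel$lat) * KM_DEG
  x0 <- max(min(rx), min(qx)); x1 <- min(max(rx), max(qx))
  y0 <- max(min(ry), min(qy)); y1 <- min(max(ry), max(qy))
  if (x0 >= x1 || y0 >= y1) return(0)
  px <- stats::runif(n_pts, x0, x1); py <- stats::runif(n_pts, y0, y1)
  hit <- pracma::inpolygon(px, py, rx, ry, boundary = TRUE) &
         pracma::inpolygon(px, py, qx, qy, boundary = TRUE)
  mean(hit) * (x1 - x0) * (y1 - y0)
}

# daily polygon-average tibble built by hand (for disparity tests)
daily_tbl <- function(geoid, date, mean_column, total_weight = 1,
                      method = "pgo") {
  tibble::tibble(geoid = geoid, window_start = as.Date(date),
                 window_end = as.Date(date), method = method,
                 mean_column = mean_column, total_weight = total_weight,
                 n_obs = 1L)
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
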