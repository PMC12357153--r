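# Screening and polygon-level / grid-level oversampling.
#
# Both polygon schemes compute, for polygon x and temporal window t,
#   mean_{x,t} = sum_t sum_i w_{i,x} Omega_i / sum_t sum_i w_{i,x}
# with w the super-Gaussian response integral (PGO) or the footprint
# overlap area (AWO). The grid baseline (AWO-Grid) applies the area weights
# to a regular lon/lat grid and then transfers cell means to polygons.

#' Screen observations on the quality-assurance value
#'
#' Keeps observations whose `qa` is strictly greater than the threshold.
#'
#' @param observations Data frame of pixel observations with a `qa` column.
#' @param threshold QA cutoff (default 0.75).
#' @return The kept rows, as a tibble. Kept/dropped counts are reported via
#'   `message()`.
#' @export
screen_qa <- function(observations, threshold = 0.75) {
  stopifnot("qa" %in% names(observations))
  obs <- tibble::as_tibble(observations)
  keep <- obs$qa > threshold
  message(sprintf("screen_qa: kept %d of %d observations (qa > %g)",
                  sum(keep), length(keep), threshold))
  obs[keep, , drop = FALSE]
}

# window keys and calendar bounds ---------------------------------------------

window_key <- function(dates, window) {
  switch(window,
    full = rep("full", length(dates)),
    daily = format(dates, "%Y-%m-%d"),
    monthly = format(dates, "%Y-%m"),
    annual = format(dates, "%Y"),
    stop("unknown window label: ", window,
         " (use one of full, daily, monthly, annual)")
  )
}

window_bounds <- function(keys, dates, window) {
  uk <- sort(unique(keys))
  if (window == "full") {
    return(tibble::tibble(key = uk, window_start = min(dates),
                          window_end = max(dates)))
  }
  start <- switch(window,
    daily = as.Date(uk),
    monthly = as.Date(paste0(uk, "-01")),
    annual = as.Date(paste0(uk, "-01-01"))
  )
  end <- switch(window,
    daily = start,
    monthly = seq_month_end(start),
    annual = as.Date(paste0(uk, "-12-31"))
  )
  tibble::tibble(key = uk, window_start = start, window_end = end)
}

seq_month_end <- function(starts) {
  vapply(as.character(starts), function(s) {
    d <- as.Date(s)
    nxt <- seq(d, by = "1 month", length.out = 2)[2]
    as.character(nxt - 1)
  }, character(1)) |> as.Date()
}

# vectorised per-pixel frame quantities (corner convention assumed)
pixel_frame_table <- function(obs, fwhm_scale = c(1, 1)) {
  kpd <- km_per_degree()
  nsc <- rep(kpd, nrow(obs))
  esc <- kpd * cos(obs$lat * pi / 180)
  m01x <- ((obs$lon0 + obs$lon1) / 2 - obs$lon) * esc
  m01y <- ((obs$lat0 + obs$lat1) / 2 - obs$lat) * nsc
  m23x <- ((obs$lon2 + obs$lon3) / 2 - obs$lon) * esc
  m23y <- ((obs$lat2 + obs$lat3) / 2 - obs$lat) * nsc
  vx <- m23x - m01x; vy <- m23y - m01y
  fwhm_x <- sqrt(vx^2 + vy^2)
  ax <- vx / fwhm_x; ay <- vy / fwhm_x
  m12x <- ((obs$lon1 + obs$lon2) / 2 - obs$lon) * esc
  m12y <- ((obs$lat1 + obs$lat2) / 2 - obs$lat) * nsc
  m30x <- ((obs$lon3 + obs$lon0) / 2 - obs$lon) * esc
  m30y <- ((obs$lat3 + obs$lat0) / 2 - obs$lat) * nsc
  fwhm_y <- sqrt((m12x - m30x)^2 + (m12y - m30y)^2)
  list(
    esc = esc, nsc = nsc, ax = ax, ay = ay, bx = -ay, by = ax,
    fwhm_x = fwhm_x * fwhm_scale[1], fwhm_y = fwhm_y * fwhm_scale[2],
    lon_min = pmin(obs$lon0, obs$lon1, obs$lon2, obs$lon3),
    lon_max = pmax(obs$lon0, obs$lon1, obs$lon2, obs$lon3),
    lat_min = pmin(obs$lat0, obs$lat1, obs$lat2, obs$lat3),
    lat_max = pmax(obs$lat0, obs$lat1, obs$lat2, obs$lat3)
  )
}

# Per-polygon PGO quadrature cells, flattened for fast gather. Polygons with
# no inside raster cell get their centroid as a single fallback cell.
prepare_pgo_cells <- function(polygons, resolution) {
  cells <- vector("list", nrow(polygons))
  for (j in seq_len(nrow(polygons))) {
    ras <- rasterize_polygon(polygons$geometry[[j]], resolution)
    if (ras$n_inside == 0) {
      ct <- geometry_centroid(polygons$geometry[[j]])
      ras <- list(lon = ct[1], lat = ct[2],
                  area_km2 = geometry_area_km2(polygons$geometry[[j]]))
    }
    cells[[j]] <- ras
  }
  counts <- vapply(cells, function(cc) length(cc$lon), integer(1))
  list(
    lon = unlist(lapply(cells, `[[`, "lon")),
    lat = unlist(lapply(cells, `[[`, "lat")),
    area = unlist(lapply(cells, `[[`, "area_km2")),
    start = cumsum(c(1L, counts[-length(counts)])),
    count = counts
  )
}

validate_observations <- function(obs) {
  need <- c("date", "lon", "lat", paste0("lon", 0:3), paste0("lat", 0:3),
            "value", "qa")
  miss <- setdiff(need, names(obs))
  if (length(miss)) {
    stop("observations are missing required columns: ",
         paste(miss, collapse = ", "))
  }
  obs <- tibble::as_tibble(obs)
  obs$date <- as.Date(obs$date)
  obs
}

validate_polygons <- function(polygons) {
  stopifnot(is.data.frame(polygons), all(c("geoid", "geometry") %in% names(polygons)))
  if (anyDuplicated(polygons$geoid)) {
    stop("duplicate geoid(s): ",
         paste(unique(polygons$geoid[duplicated(polygons$geoid)]), collapse = ", "))
  }
  polygons <- tibble::as_tibble(polygons)
  if (!"area_km2" %in% names(polygons)) {
    polygons$area_km2 <- vapply(polygons$geometry, geometry_area_km2, numeric(1))
  }
  polygons
}

#' Oversample screened observations onto administrative polygons
#'
#' Computes per-polygon, per-window weighted mean columns under the
#' physics-based super-Gaussian scheme (`"pgo"`), the area-weighted overlap
#' scheme (`"awo"`), or both in one pass.
#'
#' @param observations Screened pixel observations (see [screen_qa()]) with
#'   corner columns in the package convention.
#' @param polygons Polygon tibble with `geoid` and `geometry` list-column
#'   (and optionally `area_km2`).
#' @param method Character vector, subset of `c("pgo", "awo")`.
#' @param window Temporal window label: `"full"` (default), `"daily"`,
#'   `"monthly"` or `"annual"`.
#' @param n,m Super-Gaussian exponents (defaults 2 and 4).
#' @param resolution Polygon raster cells per side for PGO (default 10).
#' @param truncation_factor A pixel contributes to a polygon iff the polygon
#'   bounding box dilated by `truncation_factor * max(FWHM)` intersects the
#'   pixel bounding box (default 3; the response tail beyond is < 1e-4).
#' @param weight_floor A polygon is reported missing when its accumulated
#'   weight is below `weight_floor * area_km2` (PGO) or `weight_floor` km^2
#'   (AWO). Default 1e-6.
#' @param fwhm_scale Length-2 multiplier applied to the corner-derived
#'   along/across FWHMs (default `c(1, 1)`).
#' @return A tibble with columns `geoid`, `window_start`, `window_end`,
#'   `method`, `mean_column`, `total_weight`, `n_obs`, ordered by
#'   (method, geoid, window_start). `mean_column` is `NA` for polygons whose
#'   accumulated weight is below the floor.
#' @export
oversample_polygons <- function(observations, polygons,
                                method = "pgo", window = "full",
                                n = 2, m = 4, resolution = 10,
                                truncation_factor = 3, weight_floor = 1e-6,
                                fwhm_scale = c(1, 1)) {
  method <- match.arg(method, c("pgo", "awo"), several.ok = TRUE)
  polygons <- validate_polygons(polygons)
  obs <- validate_observations(observations)
  np <- nrow(polygons)
  if (np == 0) return(empty_polygon_result())

  if (nrow(obs) == 0) {
    return(dplyr::bind_rows(lapply(method, function(me) {
      tibble::tibble(geoid = polygons$geoid, window_start = as.Date(NA),
                     window_end = as.Date(NA), method = me,
                     mean_column = NA_real_, total_weight = 0, n_obs = 0L)
    })))
  }

  keys <- window_key(obs$date, window)
  bounds <- window_bounds(keys, obs$date, window)
  wk <- match(keys, bounds$key)
  nw <- nrow(bounds)

  fr <- pixel_frame_table(obs, fwhm_scale)
  pb <- t(vapply(polygons$geometry, geometry_bbox, numeric(4)))
  do_pgo <- "pgo" %in% method
  do_awo <- "awo" %in% method
  if (do_pgo) {
    cells <- prepare_pgo_cells(polygons, resolution)
    wx_all <- width_from_fwhm(fr$fwhm_x, n)
    wy_all <- width_from_fwhm(fr$fwhm_y, m)
    num_p <- matrix(0, np, nw); den_p <- matrix(0, np, nw)
    nob_p <- matrix(0L, np, nw)
  }
  if (do_awo) {
    parts_list <- lapply(polygons$geometry, as_geometry)
    num_a <- matrix(0, np, nw); den_a <- matrix(0, np, nw)
    nob_a <- matrix(0L, np, nw)
  }

  p_lon_min <- pb[, 1]; p_lat_min <- pb[, 2]; p_lon_max <- pb[, 3]; p_lat_max <- pb[, 4]
  for (i in seq_len(nrow(obs))) {
    lon <- obs$lon[i]; lat <- obs$lat[i]; val <- obs$value[i]
    esc <- fr$esc[i]; nsc <- fr$nsc[i]
    k <- wk[i]
    if (do_pgo) {
      maxf <- max(fr$fwhm_x[i], fr$fwhm_y[i])
      pad_lon <- truncation_factor * maxf / esc
      pad_lat <- truncation_factor * maxf / nsc
      cand <- which(p_lon_min - pad_lon <= fr$lon_max[i] &
                    p_lon_max + pad_lon >= fr$lon_min[i] &
                    p_lat_min - pad_lat <= fr$lat_max[i] &
                    p_lat_max + pad_lat >= fr$lat_min[i])
      if (length(cand)) {
        idx <- sequence(cells$count[cand], from = cells$start[cand])
        pid <- rep.int(cand, cells$count[cand])
        dx <- (cells$lon[idx] - lon) * esc
        dy <- (cells$lat[idx] - lat) * nsc
        x <- dx * fr$ax[i] + dy * fr$ay[i]
        y <- dx * fr$bx[i] + dy * fr$by[i]
        s <- exp(-(abs(x / wx_all[i])^n + abs(y / wy_all[i])^m))
        w <- rowsum(s * cells$area[idx], pid, reorder = FALSE)[, 1]
        num_p[cand, k] <- num_p[cand, k] + w * val
        den_p[cand, k] <- den_p[cand, k] + w
        nob_p[cand, k] <- nob_p[cand, k] + 1L
      }
    }
    if (do_awo) {
      cand <- which(p_lon_min <= fr$lon_max[i] & p_lon_max >= fr$lon_min[i] &
                    p_lat_min <= fr$lat_max[i] & p_lat_max >= fr$lat_min[i])
      if (length(cand)) {
        qx <- (c(obs$lon0[i], obs$lon1[i], obs$lon2[i], obs$lon3[i]) - lon) * esc
        qy <- (c(obs$lat0[i], obs$lat1[i], obs$lat2[i], obs$lat3[i]) - lat) * nsc
        clip <- ensure_ccw(cbind(qx, qy))
        for (j in cand) {
          a <- 0
          for (part in parts_list[[j]]) {
            for (r in seq_along(part)) {
              ring <- part[[r]]
              rkm <- cbind((ring[, 1] - lon) * esc, (ring[, 2] - lat) * nsc)
              cl <- clip_ring_convex(ensure_ccw(rkm), clip)
              if (nrow(cl) >= 3) {
                ra <- abs(ring_area_signed(cl))
                a <- a + if (r == 1L) ra else -ra
              }
            }
          }
          if (a > 0) {
            num_a[j, k] <- num_a[j, k] + a * val
            den_a[j, k] <- den_a[j, k] + a
            nob_a[j, k] <- nob_a[j, k] + 1L
          }
        }
      }
    }
  }

  out <- list()
  if (do_pgo) {
    out$pgo <- assemble_polygon_result(polygons, bounds, "pgo", num_p, den_p,
                                       nob_p, weight_floor * polygons$area_km2)
  }
  if (do_awo) {
    out$awo <- assemble_polygon_result(polygons, bounds, "awo", num_a, den_a,
                                       nob_a, rep(weight_floor, np))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$method, .data$geoid,
                 .data$window_start)
}

empty_polygon_result <- function() {
  tibble::tibble(geoid = character(), window_start = as.Date(character()),
                 window_end = as.Date(character()), method = character(),
                 mean_column = numeric(), total_weight = numeric(),
                 n_obs = integer())
}

assemble_polygon_result <- function(polygons, bounds, method, num, den, nob,
                                    floor_w) {
  nw <- nrow(bounds)
  res <- lapply(seq_len(nw), function(k) {
    mean_col <- ifelse(den[, k] >= floor_w & den[, k] > 0,
                       num[, k] / den[, k], NA_real_)
    tibble::tibble(
      geoid = polygons$geoid,
      window_start = bounds$window_start[k], window_end = bounds$window_end[k],
      method = method, mean_column = mean_col,
      total_weight = den[, k], n_obs = nob[, k]
    )
  })
  dplyr::bind_rows(res)
}

#' Oversample observations onto a regular lon/lat grid
#'
#' The area-weighted baseline: each footprint's overlap area with every grid
#' cell it touches weights its value into the cell mean. Cells are half-open
#' `[origin + k * res, origin + (k+1) * res)` with centres at `+res/2`; the
#' registration origin is explicit because shifting the grid shifts the
#' resulting spatial pattern.
#'
#' @inheritParams oversample_polygons
#' @param grid_res Cell size in degrees (default 0.01).
#' @param origin Length-2 lon/lat registration origin of the grid (default
#'   `c(0, 0)`).
#' @param bbox Optional domain `c(lon_min, lat_min, lon_max, lat_max)`;
#'   defaults to the snapped extent of the observation corners.
#' @return A tibble of class `swath_grid` with `cell_row`, `cell_col`
#'   (1-based from south-west), cell centre `lon`/`lat`, window columns,
#'   `mean_column`, `total_weight`, `n_obs`. Grid registration is stored in
#'   attribute `grid_spec`.
#' @export
oversample_grid <- function(observations, grid_res = 0.01, origin = c(0, 0),
                            window = "full", bbox = NULL) {
  obs <- validate_observations(observations)
  if (nrow(obs) == 0) stop("oversample_grid: no observations")
  fr <- pixel_frame_table(obs)
  if (is.null(bbox)) {
    bbox <- c(min(fr$lon_min), min(fr$lat_min), max(fr$lon_max), max(fr$lat_max))
  }
  # snap with a relative epsilon so footprint corners that sit exactly on
  # cell boundaries do not spill into an extra zero-overlap row/column
  snap <- function(x) round(x, 6)
  c0 <- floor(snap((bbox[1] - origin[1]) / grid_res))
  r0 <- floor(snap((bbox[2] - origin[2]) / grid_res))
  c1 <- ceiling(snap((bbox[3] - origin[1]) / grid_res)) - 1
  r1 <- ceiling(snap((bbox[4] - origin[2]) / grid_res)) - 1
  ncol_g <- as.integer(c1 - c0 + 1); nrow_g <- as.integer(r1 - r0 + 1)
  ncell <- nrow_g * ncol_g

  keys <- window_key(obs$date, window)
  bounds <- window_bounds(keys, obs$date, window)
  wk <- match(keys, bounds$key)
  num <- matrix(0, ncell, nrow(bounds)); den <- matrix(0, ncell, nrow(bounds))
  nob <- matrix(0L, ncell, nrow(bounds))

  for (i in seq_len(nrow(obs))) {
    lon <- obs$lon[i]; lat <- obs$lat[i]
    esc <- fr$esc[i]; nsc <- fr$nsc[i]; k <- wk[i]
    qx <- (c(obs$lon0[i], obs$lon1[i], obs$lon2[i], obs$lon3[i]) - lon) * esc
    qy <- (c(obs$lat0[i], obs$lat1[i], obs$lat2[i], obs$lat3[i]) - lat) * nsc
    subj <- ensure_ccw(cbind(qx, qy))
    ci <- floor((fr$lon_min[i] - origin[1]) / grid_res):
          floor((fr$lon_max[i] - origin[1]) / grid_res)
    ri <- floor((fr$lat_min[i] - origin[2]) / grid_res):
          floor((fr$lat_max[i] - origin[2]) / grid_res)
    ci <- ci[ci >= c0 & ci <= c1]; ri <- ri[ri >= r0 & ri <= r1]
    for (r in ri) for (cc in ci) {
      cell <- rect_ring(origin[1] + cc * grid_res, origin[2] + r * grid_res,
                        origin[1] + (cc + 1) * grid_res,
                        origin[2] + (r + 1) * grid_res)
      clip <- ensure_ccw(cbind((cell[, 1] - lon) * esc, (cell[, 2] - lat) * nsc))
      cl <- clip_ring_convex(subj, clip)
      if (nrow(cl) >= 3) {
        a <- abs(ring_area_signed(cl))
        if (a > 1e-12) {
          id <- (r - r0) * ncol_g + (cc - c0) + 1
          num[id, k] <- num[id, k] + a * obs$value[i]
          den[id, k] <- den[id, k] + a
          nob[id, k] <- nob[id, k] + 1L
        }
      }
    }
  }

  rows <- rep(seq_len(nrow_g), each = ncol_g)
  cols <- rep(seq_len(ncol_g), times = nrow_g)
  res <- lapply(seq_len(nrow(bounds)), function(k) {
    tibble::tibble(
      cell_row = rows, cell_col = cols,
      lon = origin[1] + (c0 + cols - 1 + 0.5) * grid_res,
      lat = origin[2] + (r0 + rows - 1 + 0.5) * grid_res,
      window_start = bounds$window_start[k], window_end = bounds$window_end[k],
      mean_column = ifelse(den[, k] > 1e-12, num[, k] / den[, k], NA_real_),
      total_weight = den[, k], n_obs = nob[, k]
    )
  })
  out <- dplyr::bind_rows(res)
  attr(out, "grid_spec") <- list(grid_res = grid_res, origin = origin,
                                 c0 = c0, r0 = r0, ncol = ncol_g, nrow = nrow_g)
  class(out) <- c("swath_grid", class(out))
  out
}

#' Assign gridded means to polygons (the AWO-Grid baseline)
#'
#' Polygons larger than a grid cell get the unweighted mean of all valid
#' cells whose centres fall inside; polygons smaller than a cell (or with no
#' cell centre inside) get the value of the cell whose centre is nearest to
#' the polygon centroid, with ties broken towards the lower (row, column)
#' index. That nearest cell being missing makes the polygon missing.
#'
#' @param grid Output of [oversample_grid()].
#' @param polygons Polygon tibble (`geoid`, `geometry`).
#' @return A polygon-average tibble with `method = "awo-grid"`.
#' @export
grid_to_polygons <- function(grid, polygons) {
  spec <- attr(grid, "grid_spec")
  if (is.null(spec)) stop("grid_to_polygons: grid lacks its grid_spec attribute")
  polygons <- validate_polygons(polygons)
  kpd <- km_per_degree()
  out <- list()
  for (wname in unique(paste(grid$window_start, grid$window_end))) {
    gw <- grid[paste(grid$window_start, grid$window_end) == wname, ]
    # row-major (row, column) order so `which.min` ties pick the lower index
    ord <- order(gw$cell_row, gw$cell_col)
    gw <- gw[ord, ]
    res <- tibble::tibble(
      geoid = polygons$geoid,
      window_start = gw$window_start[1], window_end = gw$window_end[1],
      method = "awo-grid", mean_column = NA_real_,
      total_weight = NA_real_, n_obs = NA_integer_
    )
    for (j in seq_len(nrow(polygons))) {
      ct <- geometry_centroid(polygons$geometry[[j]])
      cell_area <- (spec$grid_res * kpd * cos(ct[2] * pi / 180)) *
                   (spec$grid_res * kpd)
      inside <- integer(0)
      if (polygons$area_km2[j] > cell_area) {
        bb <- geometry_bbox(polygons$geometry[[j]])
        near <- which(gw$lon >= bb[["lon_min"]] & gw$lon <= bb[["lon_max"]] &
                      gw$lat >= bb[["lat_min"]] & gw$lat <= bb[["lat_max"]])
        if (length(near)) {
          keep <- points_in_rings(gw$lon[near], gw$lat[near],
                                  geometry_rings(polygons$geometry[[j]]))
          inside <- near[keep]
        }
      }
      if (length(inside)) {
        vals <- gw$mean_column[inside]
        res$mean_column[j] <- if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
        res$total_weight[j] <- sum(gw$total_weight[inside])
        res$n_obs[j] <- sum(gw$n_obs[inside])
      } else {
        d2 <- (gw$lon - ct[1])^2 * cos(ct[2] * pi / 180)^2 + (gw$lat - ct[2])^2
        # ties (within rounding) resolve to the lower (row, col) index
        nearest <- which(d2 - min(d2) <= 1e-12)[1]
        res$mean_column[j] <- gw$mean_column[nearest]
        res$total_weight[j] <- gw$total_weight[nearest]
        res$n_obs[j] <- gw$n_obs[nearest]
      }
    }
    out[[wname]] <- res
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$geoid, .data$window_start)
}

#' Count missing polygons per method
#'
#' @param ... Polygon-average tibbles (from [oversample_polygons()] or
#'   [grid_to_polygons()]), concatenated before counting.
#' @return A tibble with `method`, `n_polygons`, `n_missing`.
#' @export
count_missing <- function(...) {
  dplyr::bind_rows(...) |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(n_polygons = dplyr::n(),
                     n_missing = sum(is.na(.data$mean_column)),
                     .groups = "drop")
}
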