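# Seeded synthetic scenes: a smooth plume-plus-background column field with
# day-to-day lognormal variability and stagnation-day sharpening, push-broom
# swaths with across-track pixel growth and contiguous cloud gaps, a
# density-driven polygon tessellation, and demographics with a tunable
# segregation structure. Everything is deterministic under the scene seed.

with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

sum_over_terms <- function(d, amplitudes, decays) {
  v <- 0
  for (k in seq_along(amplitudes)) v <- v + amplitudes[k] * exp(-d / decays[k])
  v
}

derived_seed <- function(seed, day = 0, salt = 0) {
  ((abs(seed) %% 1000003) * 1009 + day * 97 + salt * 131071) %% 2147483646 + 1
}

#' Synthetic scene configuration
#'
#' Collects every tunable of the synthetic generators with defaults chosen
#' to emulate an urban satellite scene: a 1 deg x 1 deg domain, 300 daily
#' overpasses, two exponential plumes over a uniform background, 20%
#' contiguous cloud cover, nadir footprints of 5.5 x 3.5 km growing by a
#' factor of 2 towards the swath edge, ~200 polygons concentrated near the
#' plume cores, and moderately segregated demographics.
#'
#' @param bbox Domain `c(lon_min, lat_min, lon_max, lat_max)` in degrees.
#' @param n_days Number of daily overpasses.
#' @param seed Scene seed; all generator randomness derives from it.
#' @param start_date First observation date.
#' @param plumes Data frame with `lon`, `lat`, `amplitude` (column units,
#'   1e15 molecules/cm2) and `decay_km` per plume.
#' @param background Background column level (same units).
#' @param daily_sigma Lognormal sdlog of the day factor (mean-1 lognormal).
#' @param stagnation_fraction Fraction of days designated stagnation days.
#' @param sharpening On stagnation days amplitudes multiply and decay
#'   lengths divide by this factor (sharper, stronger plumes).
#' @param cloud_fraction Target fraction of pixels inside cloud blobs
#'   (their qa falls below 0.75).
#' @param pixel_along_km,pixel_across_km Nadir footprint extents.
#' @param growth_factor Across-track footprint width at the swath edge
#'   relative to nadir.
#' @param azimuth_deg Ground-track azimuth from north, degrees.
#' @param n_polygons Number of polygons in the tessellation.
#' @param density_amplitude,density_decay_km Splitting-density enhancement
#'   near plume cores (parallel vectors, one exponential term each; the
#'   default pairs a broad urban term with a sharp core term so cell areas
#'   span from ~0.01 km^2 downtown to hundreds of km^2 in the countryside).
#' @param pop_total Total population across the domain.
#' @param minority_base,segregation Baseline minority share and racial
#'   segregation strength `s` in `[0, 1]` (0 = uniform composition,
#'   1 = minority fully concentrated at plume cores).
#' @param low_income_base,income_segregation Same for the low-income share.
#' @param demo_decay_km Length scale of the segregation profile.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(bbox = c(-100, 39.5, -99, 40.5),
                         n_days = 300, seed = 7,
                         start_date = as.Date("2019-01-01"),
                         plumes = data.frame(
                           lon = c(-99.70, -99.33),
                           lat = c(40.10, 39.80),
                           amplitude = c(8, 5),
                           decay_km = c(12, 8)),
                         background = 1,
                         daily_sigma = 0.3,
                         stagnation_fraction = 0.05,
                         sharpening = 1.8,
                         cloud_fraction = 0.2,
                         pixel_along_km = 5.5, pixel_across_km = 3.5,
                         growth_factor = 2, azimuth_deg = 5,
                         n_polygons = 200,
                         density_amplitude = c(300, 5e4),
                         density_decay_km = c(10, 0.6),
                         pop_total = 1e6,
                         minority_base = 0.3, segregation = 0.5,
                         low_income_base = 0.25, income_segregation = 0.5,
                         demo_decay_km = 15) {
  cfg <- as.list(environment())
  stopifnot(cfg$cloud_fraction >= 0, cfg$cloud_fraction < 1,
            cfg$segregation >= 0, cfg$segregation <= 1,
            cfg$income_segregation >= 0, cfg$income_segregation <= 1,
            all(cfg$plumes$amplitude >= 0), cfg$n_polygons >= 4)
  cfg$start_date <- as.Date(cfg$start_date)
  structure(cfg, class = "scene_config")
}

domain_center <- function(config) {
  c(lon = (config$bbox[1] + config$bbox[3]) / 2,
    lat = (config$bbox[2] + config$bbox[4]) / 2)
}

# km displacement from the domain centre (equirectangular at centre latitude)
domain_km <- function(config, lon, lat) {
  ct <- domain_center(config)
  cbind((lon - ct[["lon"]]) * km_per_degree() * cos(ct[["lat"]] * pi / 180),
        (lat - ct[["lat"]]) * km_per_degree())
}

#' Designated stagnation days of a scene
#'
#' @param config A [scene_config()].
#' @return Sorted integer day indices (1-based), drawn once from the scene
#'   seed.
#' @export
stagnation_days <- function(config) {
  k <- ceiling(config$stagnation_fraction * config$n_days)
  if (k == 0) return(integer(0))
  with_seed(derived_seed(config$seed, salt = 1),
            sort(sample.int(config$n_days, k)))
}

daily_factor <- function(config, day) {
  with_seed(derived_seed(config$seed, day, salt = 2),
            exp(stats::rnorm(1, 0, config$daily_sigma) -
                config$daily_sigma^2 / 2))
}

#' Continuous column field of one day
#'
#' `background + sum_j a_j * exp(-d_j / L_j)`, all multiplied by a seeded
#' daily lognormal factor; on designated stagnation days amplitudes grow and
#' decay lengths shrink by the sharpening factor.
#'
#' @param config A [scene_config()].
#' @param day 1-based day index.
#' @return A vectorised function `f(lon, lat)` returning column values.
#' @export
generate_field <- function(config, day) {
  stag <- day %in% stagnation_days(config)
  amp <- config$plumes$amplitude * if (stag) config$sharpening else 1
  dec <- config$plumes$decay_km / if (stag) config$sharpening else 1
  fac <- daily_factor(config, day)
  force(config)
  function(lon, lat) {
    km <- domain_km(config, lon, lat)
    v <- rep(config$background, length(lon))
    for (j in seq_len(nrow(config$plumes))) {
      pj <- domain_km(config, config$plumes$lon[j], config$plumes$lat[j])
      d <- sqrt((km[, 1] - pj[1])^2 + (km[, 2] - pj[2])^2)
      v <- v + amp[j] * exp(-d / dec[j])
    }
    v * fac
  }
}

#' Generate one day's swath of footprints
#'
#' Scanlines of quadrilateral footprints tile the domain along the ground
#' track azimuth; across-track footprint width grows quadratically from the
#' swath centre up to `growth_factor` times the nadir width at the edge.
#' Pixel values are footprint means of the field over a 5 x 5 sample; qa is
#' drawn so pixels inside contiguous seeded cloud blobs fall below 0.75.
#'
#' @param config A [scene_config()].
#' @param day 1-based day index.
#' @param field Optional field function (defaults to
#'   `generate_field(config, day)`).
#' @return A tibble of pixel observations (`id`, `date`, `lon`, `lat`,
#'   corner columns, `value`, `qa`) with corners already in the package
#'   convention.
#' @export
generate_swath <- function(config, day, field = NULL) {
  if (is.null(field)) field <- generate_field(config, day)
  ct <- domain_center(config)
  kpd <- km_per_degree()
  esc <- kpd * cos(ct[["lat"]] * pi / 180)
  az <- config$azimuth_deg * pi / 180
  A <- c(sin(az), cos(az))      # along-track unit (east, north)
  U <- c(cos(az), -sin(az))     # u axis; across-track axis is -U
  corners_km <- domain_km(config, config$bbox[c(1, 3, 3, 1)],
                          config$bbox[c(2, 2, 4, 4)])
  u_rng <- range(corners_km %*% U)
  v_rng <- range(corners_km %*% A)
  h <- config$pixel_along_km
  w0 <- config$pixel_across_km
  uc <- mean(u_rng); uhalf <- diff(u_rng) / 2
  width_at <- function(u) {
    w0 * (1 + (config$growth_factor - 1) * ((u - uc) / uhalf)^2)
  }

  rows <- list()
  v <- v_rng[1]
  while (v < v_rng[2]) {
    u <- u_rng[1]
    while (u < u_rng[2]) {
      w <- width_at(u)
      rows[[length(rows) + 1L]] <- c(u, u + w, v, v + h)
      u <- u + w
    }
    v <- v + h
  }
  q <- do.call(rbind, rows)   # u_left, u_right, v_low, v_high
  npx <- nrow(q)

  km_to_lonlat <- function(kx, ky) {
    cbind(ct[["lon"]] + kx / esc, ct[["lat"]] + ky / kpd)
  }
  uv_to_lonlat <- function(u, v) km_to_lonlat(u * U[1] + v * A[1],
                                              u * U[2] + v * A[2])
  # corner convention: 0 = (-along, -across) = (v low, u high)
  c0 <- uv_to_lonlat(q[, 2], q[, 3]); c1 <- uv_to_lonlat(q[, 1], q[, 3])
  c2 <- uv_to_lonlat(q[, 1], q[, 4]); c3 <- uv_to_lonlat(q[, 2], q[, 4])
  cen <- uv_to_lonlat((q[, 1] + q[, 2]) / 2, (q[, 3] + q[, 4]) / 2)

  # footprint mean of the field over a 5 x 5 midpoint sample
  fr <- (seq_len(5) - 0.5) / 5
  su <- rep(fr, times = 5); sv <- rep(fr, each = 5)
  vals <- matrix(0, npx, 25)
  for (s in seq_len(25)) {
    p <- uv_to_lonlat(q[, 1] + su[s] * (q[, 2] - q[, 1]),
                      q[, 3] + sv[s] * (q[, 4] - q[, 3]))
    vals[, s] <- field(p[, 1], p[, 2])
  }
  value <- rowMeans(vals)

  qa <- with_seed(derived_seed(config$seed, day, salt = 3), {
    cloudy <- rep(FALSE, npx)
    pk <- domain_km(config, cen[, 1], cen[, 2])
    if (config$cloud_fraction > 0) {
      tries <- 0
      while (mean(cloudy) < config$cloud_fraction && tries < 200) {
        bc <- c(stats::runif(1, min(pk[, 1]), max(pk[, 1])),
                stats::runif(1, min(pk[, 2]), max(pk[, 2])))
        br <- stats::runif(1, 5, 20)
        cloudy <- cloudy | ((pk[, 1] - bc[1])^2 + (pk[, 2] - bc[2])^2 < br^2)
        tries <- tries + 1
      }
    }
    ifelse(cloudy, stats::runif(npx, 0, 0.6), stats::runif(npx, 0.8, 1))
  })

  tibble::tibble(
    id = sprintf("d%03d_p%05d", day, seq_len(npx)),
    date = config$start_date + day - 1,
    lon = cen[, 1], lat = cen[, 2],
    lon0 = c0[, 1], lat0 = c0[, 2], lon1 = c1[, 1], lat1 = c1[, 2],
    lon2 = c2[, 1], lat2 = c2[, 2], lon3 = c3[, 1], lat3 = c3[, 2],
    value = value, qa = qa
  )
}

#' Generate the polygon tessellation
#'
#' A seeded recursive rectangle partition: starting from the domain, the
#' leaf with the largest mass (splitting density integrated over the leaf,
#' density enhanced near plume cores) is split across its longer side at a
#' jittered fraction, until `n_polygons` leaves exist. The leaves partition
#' the domain exactly; cells are small near plume cores ("urban") and
#' coarse elsewhere. Each polygon carries a `region_id` from a 2 x 2 coarse
#' partition of the domain.
#'
#' @param config A [scene_config()].
#' @return A tibble `geoid`, `region_id`, `area_km2`, `centroid_lon`,
#'   `centroid_lat`, `geometry`.
#' @export
generate_polygons <- function(config) {
  density_at <- function(lon, lat) {
    km <- domain_km(config, lon, lat)
    d <- Inf
    for (j in seq_len(nrow(config$plumes))) {
      pj <- domain_km(config, config$plumes$lon[j], config$plumes$lat[j])
      d <- pmin(d, sqrt((km[, 1] - pj[1])^2 + (km[, 2] - pj[2])^2))
    }
    1 + sum_over_terms(d, config$density_amplitude, config$density_decay_km)
  }
  ct <- domain_center(config)
  esc <- km_per_degree() * cos(ct[["lat"]] * pi / 180)
  leaf_mass <- function(lf) {
    area <- (lf[3] - lf[1]) * esc * (lf[4] - lf[2]) * km_per_degree()
    density_at((lf[1] + lf[3]) / 2, (lf[2] + lf[4]) / 2) * area
  }
  leaves <- list(config$bbox)
  masses <- leaf_mass(config$bbox)
  with_seed(derived_seed(config$seed, salt = 4), {
    while (length(leaves) < config$n_polygons) {
      i <- which.max(masses)
      lf <- leaves[[i]]
      f <- stats::runif(1, 0.4, 0.6)
      wide <- (lf[3] - lf[1]) * esc >= (lf[4] - lf[2]) * km_per_degree()
      if (wide) {
        cut <- lf[1] + f * (lf[3] - lf[1])
        a <- c(lf[1], lf[2], cut, lf[4]); b <- c(cut, lf[2], lf[3], lf[4])
      } else {
        cut <- lf[2] + f * (lf[4] - lf[2])
        a <- c(lf[1], lf[2], lf[3], cut); b <- c(lf[1], cut, lf[3], lf[4])
      }
      leaves[[i]] <- a
      leaves[[length(leaves) + 1L]] <- b
      masses[i] <- leaf_mass(a)
      masses[length(leaves)] <- leaf_mass(b)
    }
  })
  n <- length(leaves)
  geom <- lapply(leaves, function(lf) list(list(rect_ring(lf[1], lf[2], lf[3], lf[4]))))
  cx <- vapply(leaves, function(lf) (lf[1] + lf[3]) / 2, numeric(1))
  cy <- vapply(leaves, function(lf) (lf[2] + lf[4]) / 2, numeric(1))
  region <- paste0("R", ifelse(cy >= ct[["lat"]], 0, 2) +
                        ifelse(cx >= ct[["lon"]], 2, 1))
  ord <- order(cy, cx)
  tibble::tibble(
    geoid = sprintf("BG%05d", seq_len(n)),
    region_id = region[ord],
    area_km2 = vapply(geom[ord], geometry_area_km2, numeric(1)),
    centroid_lon = cx[ord], centroid_lat = cy[ord],
    geometry = geom[ord]
  )
}

#' Generate demographics with a tunable segregation structure
#'
#' Each polygon's minority share is `(1 - s) * base + s * exp(-d / L)` with
#' `d` the centroid distance to the nearest plume core, so `s = 0` gives a
#' spatially uniform composition (all downstream disparities exactly zero)
#' and `s = 1` concentrates minority populations at the plume cores. The
#' low-income share is generated analogously with its own segregation
#' parameter; a fixed 10% of each polygon sits in the excluded middle
#' income band. Total population is proportional to 1/area (denser where
#' polygons are small).
#'
#' @param polygons Output of [generate_polygons()].
#' @param config A [scene_config()].
#' @return A tibble `geoid`, `white`, `hispanic`, `black`, `asian`,
#'   `native_american`, `income_below_124`, `income_above_150`.
#' @export
generate_demographics <- function(polygons, config) {
  km <- domain_km(config, polygons$centroid_lon, polygons$centroid_lat)
  d <- Inf
  for (j in seq_len(nrow(config$plumes))) {
    pj <- domain_km(config, config$plumes$lon[j], config$plumes$lat[j])
    d <- pmin(d, sqrt((km[, 1] - pj[1])^2 + (km[, 2] - pj[2])^2))
  }
  g <- exp(-d / config$demo_decay_km)
  s <- config$segregation
  mshare <- pmin((1 - s) * config$minority_base + s * g, 0.95)
  inv <- 1 / polygons$area_km2
  pop <- config$pop_total * inv / sum(inv)
  si <- config$income_segregation
  lshare <- pmin((1 - si) * config$low_income_base + si * g, 0.9)
  minority_split <- c(hispanic = 0.5, black = 0.3, asian = 0.15,
                      native_american = 0.05)
  tibble::tibble(
    geoid = polygons$geoid,
    white = pop * (1 - mshare),
    hispanic = pop * mshare * minority_split[["hispanic"]],
    black = pop * mshare * minority_split[["black"]],
    asian = pop * mshare * minority_split[["asian"]],
    native_american = pop * mshare * minority_split[["native_american"]],
    income_below_124 = pop * lshare,
    income_above_150 = pop * (1 - lshare - 0.1)
  )
}

#' Generate a complete synthetic scene
#'
#' @param config A [scene_config()].
#' @param days Day indices to simulate (default all `n_days`).
#' @param progress Report per-day progress via `message()` every 50 days.
#' @return A list with `config`, `polygons`, `demographics`, `region_map`,
#'   `observations` (all days bound together) and `stagnation_days`.
#' @export
simulate_scene <- function(config = scene_config(), days = seq_len(config$n_days),
                           progress = FALSE) {
  polygons <- generate_polygons(config)
  obs <- vector("list", length(days))
  for (i in seq_along(days)) {
    obs[[i]] <- generate_swath(config, days[i])
    if (progress && i %% 50 == 0) message("simulated day ", i, "/", length(days))
  }
  list(
    config = config,
    polygons = polygons,
    demographics = generate_demographics(polygons, config),
    region_map = polygons[, c("geoid", "region_id")],
    observations = dplyr::bind_rows(obs),
    stagnation_days = stagnation_days(config)
  )
}
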