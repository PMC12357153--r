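# Readers and writers: flat-table Level-2 swaths (CSV), GeoJSON polygons,
# demographic and region-map CSVs, result tables (CSV or GeoJSON join), and
# the run manifest. Everything the package writes it can read back
# losslessly; missing values are empty CSV fields, never sentinels.

swath_columns <- c("id", "date", "lon", "lat",
                   paste0(rep(c("lon", "lat"), 4), rep(0:3, each = 2)),
                   "value", "qa")

#' Read a Level-2 swath table
#'
#' Reads the flat CSV dialect (one row per footprint: `id, date, lon, lat,
#' lon0..lon3, lat0..lat3, value, qa`), validates it, drops malformed rows
#' (non-finite coordinates or value, qa outside `[0, 1]`) with a count
#' message, and normalises the corner order to the package convention.
#'
#' @param path Path to the CSV file.
#' @return A tibble of pixel observations.
#' @export
read_l2_swath <- function(path) {
  if (!file.exists(path)) stop("read_l2_swath: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(swath_columns, names(df))
  if (length(miss)) {
    stop("read_l2_swath: missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  num <- setdiff(swath_columns, c("id", "date"))
  ok <- Reduce(`&`, lapply(df[num], is.finite)) & df$qa >= 0 & df$qa <= 1
  if (any(!ok)) {
    message("read_l2_swath: skipped ", sum(!ok), " malformed row(s)")
  }
  df <- df[ok, swath_columns]
  df$date <- as.Date(df$date)
  normalize_corners(tibble::as_tibble(df))
}

#' Write a swath table to CSV
#'
#' @param observations Pixel-observation tibble.
#' @param path Output path.
#' @export
write_swath_csv <- function(observations, path) {
  df <- as.data.frame(observations)[, swath_columns]
  df$date <- format(as.Date(df$date), "%Y-%m-%d")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# --- GeoJSON polygons --------------------------------------------------------

close_ring <- function(ring) {
  if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
}

open_ring <- function(coords) {
  m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
  if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  m
}

#' Write polygons as a GeoJSON FeatureCollection
#'
#' Features carry `GEOID` (and `region_id` if present) as properties;
#' single-part geometries become `Polygon`, multi-part `MultiPolygon`.
#'
#' @param polygons Polygon tibble with `geoid` and `geometry`.
#' @param path Output path.
#' @export
write_polygons_geojson <- function(polygons, path) {
  feats <- lapply(seq_len(nrow(polygons)), function(i) {
    parts <- as_geometry(polygons$geometry[[i]])
    geom <- if (length(parts) == 1) {
      list(type = "Polygon", coordinates = lapply(parts[[1]], close_ring))
    } else {
      list(type = "MultiPolygon",
           coordinates = lapply(parts, function(p) lapply(p, close_ring)))
    }
    props <- list(GEOID = polygons$geoid[i])
    if ("region_id" %in% names(polygons)) {
      props$region_id <- polygons$region_id[i]
    }
    list(type = "Feature", properties = props, geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read polygons from GeoJSON
#'
#' Accepts `Polygon` and `MultiPolygon` features; every feature must carry a
#' `GEOID` property and geoids must be unique. Areas are computed in km^2.
#'
#' @param path Path to a GeoJSON FeatureCollection.
#' @return A polygon tibble (`geoid`, optional `region_id`, `area_km2`,
#'   `geometry`).
#' @export
read_polygons <- function(path) {
  if (!file.exists(path)) stop("read_polygons: no such file: ", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features
  if (is.null(feats)) stop("read_polygons: not a GeoJSON FeatureCollection")
  geoid <- character(length(feats))
  region <- rep(NA_character_, length(feats))
  geom <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    if (is.null(f$properties$GEOID)) {
      stop("read_polygons: feature ", i, " lacks a GEOID property")
    }
    geoid[i] <- as.character(f$properties$GEOID)
    if (!is.null(f$properties$region_id)) {
      region[i] <- as.character(f$properties$region_id)
    }
    g <- f$geometry
    geom[[i]] <- switch(g$type,
      Polygon = list(lapply(g$coordinates, open_ring)),
      MultiPolygon = lapply(g$coordinates, function(p) lapply(p, open_ring)),
      stop("read_polygons: unsupported geometry type: ", g$type)
    )
  }
  if (anyDuplicated(geoid)) {
    stop("read_polygons: duplicate GEOID(s): ",
         paste(unique(geoid[duplicated(geoid)]), collapse = ", "))
  }
  out <- tibble::tibble(
    geoid = geoid,
    area_km2 = vapply(geom, geometry_area_km2, numeric(1)),
    geometry = geom
  )
  if (!all(is.na(region))) out$region_id <- region
  out
}

#' Read a demographic table
#'
#' CSV keyed by `geoid` with non-negative population columns `white`,
#' `hispanic`, `black`, `asian`, `native_american`, `income_below_124`,
#' `income_above_150`.
#'
#' @param path Path to the CSV file.
#' @return A tibble.
#' @export
read_demographics <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(geoid = "character"))
  need <- c("geoid", "white", unlist(demographic_groups[c("minority",
            "low_income", "high_income")], use.names = FALSE))
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("read_demographics: missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  pops <- df[setdiff(need, "geoid")]
  if (any(vapply(pops, function(x) any(is.na(x) | x < 0), logical(1)))) {
    stop("read_demographics: negative or missing population count(s)")
  }
  tibble::as_tibble(df[need])
}

#' Read a geoid-to-region map
#'
#' @param path CSV with columns `geoid`, `region_id`.
#' @return A tibble.
#' @export
read_region_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("geoid", "region_id") %in% names(df))) {
    stop("read_region_map: need columns geoid, region_id")
  }
  tibble::as_tibble(df[c("geoid", "region_id")])
}

#' Write polygon-average results
#'
#' CSV mode writes `geoid, window_start, window_end, method,
#' mean_column_1e15, total_weight, n_obs` with missing means as empty
#' fields, rows ordered by (geoid, window_start). GeoJSON-join mode attaches
#' each window's mean as a feature property of the supplied polygons,
#' preserving every feature.
#'
#' @param results Polygon-average tibble.
#' @param path Output path.
#' @param mode `"csv"` or `"geojson-join"`.
#' @param polygons Polygon tibble (required for `"geojson-join"`).
#' @export
write_results <- function(results, path, mode = c("csv", "geojson-join"),
                          polygons = NULL) {
  mode <- match.arg(mode)
  if (nrow(results) == 0) stop("write_results: empty results")
  res <- dplyr::arrange(results, .data$geoid, .data$window_start)
  if (mode == "csv") {
    df <- data.frame(
      geoid = res$geoid,
      window_start = format(res$window_start, "%Y-%m-%d"),
      window_end = format(res$window_end, "%Y-%m-%d"),
      method = res$method,
      mean_column_1e15 = res$mean_column,
      total_weight = res$total_weight,
      n_obs = res$n_obs
    )
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
    return(invisible(path))
  }
  if (is.null(polygons)) stop("write_results: geojson-join needs polygons")
  gj_tmp <- tempfile(fileext = ".geojson")
  write_polygons_geojson(polygons, gj_tmp)
  gj <- jsonlite::fromJSON(gj_tmp, simplifyVector = FALSE)
  unlink(gj_tmp)
  key <- split(res, res$geoid)
  gj$features <- lapply(gj$features, function(f) {
    rows <- key[[f$properties$GEOID]]
    if (!is.null(rows)) {
      for (i in seq_len(nrow(rows))) {
        nm <- paste0("mean_", rows$method[i], "_",
                     format(rows$window_start[i], "%Y%m%d"))
        f$properties[[nm]] <- rows$mean_column[i]
      }
    }
    f
  })
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a polygon-average result CSV
#'
#' @param path Path written by [write_results()] in CSV mode.
#' @return A polygon-average tibble.
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(geoid = "character"))
  tibble::tibble(
    geoid = df$geoid,
    window_start = as.Date(df$window_start),
    window_end = as.Date(df$window_end),
    method = df$method,
    mean_column = df$mean_column_1e15,
    total_weight = df$total_weight,
    n_obs = as.integer(df$n_obs)
  )
}

#' Write a machine-readable run manifest
#'
#' Records the fully resolved configuration, input counts and output paths
#' of a run as JSON; re-running from the manifest reproduces the outputs for
#' deterministic methods.
#'
#' @param path Output path.
#' @param config Named list of resolved settings.
#' @param inputs,outputs Named lists (counts, paths).
#' @export
write_manifest <- function(path, config, inputs = list(), outputs = list()) {
  config <- lapply(config, function(x) if (inherits(x, "Date")) format(x) else x)
  jsonlite::write_json(list(config = config, inputs = inputs,
                            outputs = outputs),
                       path, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}
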