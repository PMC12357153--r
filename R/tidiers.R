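# broom-style accessors and ggplot2 autoplot methods for the disparity
# report and polygon-average results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a disparity report
#'
#' One row per region, window and disparity dimension (race, income), with
#' the group means and the percent disparity in long form.
#'
#' @param x A `disparity_report`.
#' @param ... Unused.
#' @return A tibble with `region_id`, `window`, `dimension`,
#'   `reference_mean`, `comparison_mean`, `disparity_pct`.
#' @exportS3Method generics::tidy
tidy.disparity_report <- function(x, ...) {
  base <- tibble::as_tibble(unclass(x))
  race <- dplyr::transmute(base,
    region_id = .data$region_id, window = .data$window, dimension = "race",
    reference_mean = .data$white_mean, comparison_mean = .data$minority_mean,
    disparity_pct = .data$race_disparity_pct)
  income <- dplyr::transmute(base,
    region_id = .data$region_id, window = .data$window, dimension = "income",
    reference_mean = .data$high_income_mean,
    comparison_mean = .data$low_income_mean,
    disparity_pct = .data$income_disparity_pct)
  dplyr::arrange(dplyr::bind_rows(race, income),
                 .data$region_id, .data$window, .data$dimension)
}

#' Summarise a disparity report
#'
#' @param x A `disparity_report`.
#' @param ... Unused.
#' @return A one-row tibble: number of regions, the share of regions with a
#'   positive full-window racial/ethnic and income disparity, and the share
#'   of regions whose racial/ethnic disparity increases on polluted days.
#' @exportS3Method generics::glance
glance.disparity_report <- function(x, ...) {
  full <- x[x$window == "full", ]
  tibble::tibble(
    n_regions = nrow(full),
    frac_race_positive = mean(full$race_disparity_pct > 0, na.rm = TRUE),
    frac_income_positive = mean(full$income_disparity_pct > 0, na.rm = TRUE),
    frac_race_increase_top_days =
      mean(full$race_disparity_change_pts > 0, na.rm = TRUE)
  )
}

#' Plot a disparity report
#'
#' Dot plot of the racial/ethnic and income disparity per region,
#' full-window versus most-polluted-days.
#'
#' @param object A `disparity_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.disparity_report <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$disparity_pct,
                                   y = .data$region_id,
                                   colour = .data$window)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~.data$dimension) +
    ggplot2::labs(x = "relative disparity (%)", y = NULL,
                  colour = "window") +
    ggplot2::theme_minimal()
}

#' Plot polygon-average results as a filled polygon map
#'
#' @param results A polygon-average tibble (one method and window).
#' @param polygons The polygon tibble the results refer to.
#' @return A ggplot object (equirectangular lon/lat map filled by
#'   `mean_column`).
#' @export
plot_polygon_means <- function(results, polygons) {
  res <- dplyr::distinct(results, .data$geoid, .keep_all = TRUE)
  shapes <- lapply(seq_len(nrow(polygons)), function(i) {
    ring <- as_geometry(polygons$geometry[[i]])[[1]][[1]]
    tibble::tibble(geoid = polygons$geoid[i], lon = ring[, 1], lat = ring[, 2])
  })
  df <- dplyr::left_join(dplyr::bind_rows(shapes),
                         res[, c("geoid", "mean_column")], by = "geoid")
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat, group = .data$geoid,
                                   fill = .data$mean_column)) +
    ggplot2::geom_polygon(colour = NA) +
    ggplot2::coord_fixed(1 / cos(mean(df$lat) * pi / 180)) +
    ggplot2::scale_fill_viridis_c(name = expression(
      "column (" * 10^15 ~ "molec cm"^-2 * ")")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
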