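# Population-weighted exposure statistics by demographic group, relative
# disparity metrics, polluted-day selection, and normalized spatial
# gradients, per region (CBSA-like grouping).
#
# Group definitions follow the exposure-disparity literature: the
# racial/ethnic comparison pools Hispanic, Black, Asian and Native American
# populations into a single "minority" group against white non-Hispanic;
# the income comparison contrasts households with income-to-poverty ratio
# below 1.24 ("low income") against above 1.5 ("high income"), with the
# middle band excluded.

#' Population-weighted mean exposure
#'
#' `sum(pop * value) / sum(pop)` over units where both the value and the
#' population are present; units with a missing value are excluded from
#' numerator and denominator alike.
#'
#' @param values Named numeric vector (or plain vector) of per-unit exposure.
#' @param populations Numeric vector of matching population counts.
#' @return The weighted mean, or `NA` if the usable population is zero.
#' @export
population_weighted_mean <- function(values, populations) {
  ok <- !is.na(values) & !is.na(populations) & populations > 0
  if (!any(ok) || sum(populations[ok]) <= 0) return(NA_real_)
  sum(populations[ok] * values[ok]) / sum(populations[ok])
}

#' Relative disparity between two group means
#'
#' `100 * (comparison - reference) / reference`; positive values mean the
#' comparison group (minority or low-income) is the more exposed one.
#'
#' @param reference_mean,comparison_mean Group mean exposures (reference
#'   must be positive).
#' @return Percent relative difference, `NA` when undefined.
#' @export
relative_disparity <- function(reference_mean, comparison_mean) {
  ifelse(is.na(reference_mean) | is.na(comparison_mean) | reference_mean <= 0,
         NA_real_,
         100 * (comparison_mean - reference_mean) / reference_mean)
}

#' Select the most polluted days of a region
#'
#' Ranks valid days by the regional daily mean (unweighted over non-missing
#' polygons) and returns the top fraction. A day is valid when at least
#' `min_coverage` of the region's polygons are non-missing, guarding
#' against cloud-biased day selection.
#'
#' @param daily A tibble of daily polygon averages for one region, with
#'   columns `geoid`, `window_start` (the day) and `mean_column`.
#' @param fraction Fraction of valid days to select (default 0.05).
#' @param min_coverage Minimum fraction of non-missing polygons for a day to
#'   be valid (default 0.5).
#' @param n_polygons Total polygons in the region; defaults to the number of
#'   distinct geoids present in `daily`.
#' @return A `Date` vector of the `ceiling(fraction * n_valid)` days with
#'   the highest regional mean; ties at the boundary resolve to the earlier
#'   date. Empty (with a warning) when no day is valid.
#' @export
select_polluted_days <- function(daily, fraction = 0.05, min_coverage = 0.5,
                                 n_polygons = NULL) {
  if (is.null(n_polygons)) n_polygons <- dplyr::n_distinct(daily$geoid)
  day_stats <- daily |>
    dplyr::group_by(date = .data$window_start) |>
    dplyr::summarise(n_valid = sum(!is.na(.data$mean_column)),
                     regional_mean = mean(.data$mean_column, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::filter(.data$n_valid >= min_coverage * n_polygons)
  if (nrow(day_stats) == 0) {
    warning("select_polluted_days: no valid days")
    return(as.Date(character()))
  }
  if (nrow(day_stats) < 20) {
    warning("select_polluted_days: only ", nrow(day_stats),
            " valid days; top-fraction selection is noisy")
  }
  k <- ceiling(fraction * nrow(day_stats))
  ord <- order(-day_stats$regional_mean, day_stats$date)
  sort(day_stats$date[ord[seq_len(k)]])
}

#' Normalized spatial gradient within a region
#'
#' Each polygon's value divided by the regional maximum, so the most
#' polluted polygon maps to 1 and the shape of the field is comparable
#' across absolute levels.
#'
#' @param values Named numeric vector of polygon values (names = geoids).
#' @return Named numeric vector in (0, 1]; empty if all values are missing
#'   or the maximum is not positive.
#' @export
normalized_gradient <- function(values) {
  ok <- !is.na(values)
  if (!any(ok)) return(stats::setNames(numeric(0), character(0)))
  mx <- max(values[ok])
  if (mx <= 0) return(stats::setNames(numeric(0), character(0)))
  values[ok] / mx
}

demographic_groups <- list(
  reference_race = "white",
  minority = c("hispanic", "black", "asian", "native_american"),
  low_income = "income_below_124",
  high_income = "income_above_150"
)

#' Per-region exposure-disparity report
#'
#' For every region: population-weighted group means and relative
#' disparities (racial/ethnic and income) over the full window and over the
#' top-fraction most polluted days, plus the polluted-minus-baseline
#' disparity change in percentage points.
#'
#' @param daily Daily polygon averages (one method) as returned by
#'   [oversample_polygons()] with `window = "daily"`.
#' @param demographics Demographic tibble keyed by `geoid` with columns
#'   `white`, `hispanic`, `black`, `asian`, `native_american`,
#'   `income_below_124`, `income_above_150`.
#' @param region_map Tibble `geoid`, `region_id`. Polygons missing from the
#'   map are excluded (count reported via `message()`).
#' @param top_fraction Fraction of days for the polluted-day window
#'   (default 0.05).
#' @param min_coverage Day-validity coverage rule for
#'   [select_polluted_days()].
#' @return A tibble of class `disparity_report`: one row per region and
#'   window (`"full"`, `"top-days"`) with group means (same units as
#'   `mean_column`), `exposure` (all-group population-weighted mean),
#'   `race_disparity_pct`, `income_disparity_pct`, `n_polygons`, `n_days`,
#'   and per-region `race_disparity_change_pts` /
#'   `income_disparity_change_pts` (top-days minus full, percentage points).
#' @export
disparity_report <- function(daily, demographics, region_map,
                             top_fraction = 0.05, min_coverage = 0.5) {
  stopifnot(all(c("geoid", "region_id") %in% names(region_map)))
  unmatched <- setdiff(unique(daily$geoid), region_map$geoid)
  if (length(unmatched)) {
    message("disparity_report: ", length(unmatched),
            " polygon(s) missing from the region map; excluded")
  }
  dd <- dplyr::inner_join(daily, region_map, by = "geoid")
  rows <- list()
  for (rid in sort(unique(dd$region_id))) {
    dr <- dd[dd$region_id == rid, ]
    demo <- demographics[demographics$geoid %in% unique(dr$geoid), ]
    if (nrow(demo) == 0) {
      message("disparity_report: region ", rid,
              " has no demographic coverage; skipped")
      next
    }
    np <- dplyr::n_distinct(dr$geoid)
    top <- select_polluted_days(dr, fraction = top_fraction,
                                min_coverage = min_coverage, n_polygons = np)
    for (win in c("full", "top-days")) {
      sel <- if (win == "full") dr else dr[dr$window_start %in% top, ]
      if (nrow(sel) == 0) next
      expo <- recombine_windows(sel)
      rows[[length(rows) + 1L]] <- region_disparity_row(
        rid, win, expo, demo, n_days = dplyr::n_distinct(sel$window_start))
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out)) {
    delta <- out |>
      dplyr::select("region_id", "window", "race_disparity_pct",
                    "income_disparity_pct") |>
      tidyr::pivot_wider(names_from = "window",
                         values_from = c("race_disparity_pct",
                                         "income_disparity_pct"))
    delta$race_disparity_change_pts <-
      delta$`race_disparity_pct_top-days` - delta$race_disparity_pct_full
    delta$income_disparity_change_pts <-
      delta$`income_disparity_pct_top-days` - delta$income_disparity_pct_full
    out <- dplyr::left_join(
      out,
      dplyr::select(delta, "region_id", "race_disparity_change_pts",
                    "income_disparity_change_pts"),
      by = "region_id")
  }
  class(out) <- c("disparity_report", class(out))
  out
}

# Exactly recombine polygon means across a set of windows: the weighted mean
# over the union of windows equals sum(mean * weight) / sum(weight), the
# window-additivity identity of the oversampler.
recombine_windows <- function(daily) {
  daily |>
    dplyr::group_by(.data$geoid) |>
    dplyr::summarise(
      mean_column = {
        ok <- !is.na(.data$mean_column)
        if (!any(ok)) NA_real_ else
          sum(.data$mean_column[ok] * .data$total_weight[ok]) /
            sum(.data$total_weight[ok])
      },
      .groups = "drop")
}

region_disparity_row <- function(region_id, window, expo, demo, n_days) {
  x <- dplyr::inner_join(expo, demo, by = "geoid")
  gm <- function(cols) {
    pop <- rowSums(as.matrix(x[, cols, drop = FALSE]))
    population_weighted_mean(x$mean_column, pop)
  }
  white <- gm(demographic_groups$reference_race)
  minority <- gm(demographic_groups$minority)
  low <- gm(demographic_groups$low_income)
  high <- gm(demographic_groups$high_income)
  all_groups <- gm(unlist(demographic_groups))
  tibble::tibble(
    region_id = region_id, window = window,
    exposure = all_groups,
    white_mean = white, minority_mean = minority,
    low_income_mean = low, high_income_mean = high,
    race_disparity_pct = relative_disparity(white, minority),
    income_disparity_pct = relative_disparity(high, low),
    n_polygons = sum(!is.na(x$mean_column)), n_days = n_days
  )
}
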