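test_that("population weighting and relative disparity follow their definitions", {
  expect_equal(population_weighted_mean(c(2, 4), c(1, 1)), 3)
  expect_equal(population_weighted_mean(c(2, 4), c(1, 3)), 3.5)
  expect_equal(population_weighted_mean(5.2, 10), 5.2)
  # missing values drop out of numerator and denominator
  expect_equal(population_weighted_mean(c(2, NA, 4), c(1, 100, 3)), 3.5)
  expect_true(is.na(population_weighted_mean(c(2, 4), c(0, 0))))

  expect_equal(relative_disparity(2, 3), 50)
  expect_equal(relative_disparity(3, 3), 0)
  expect_lt(relative_disparity(3, 2), 0)
  expect_true(is.na(relative_disparity(0, 3)))
})

test_that("polluted-day selection ranks valid days and breaks ties early", {
  dates <- as.Date("2021-01-01") + 0:99
  daily <- dplyr::bind_rows(lapply(seq_along(dates), function(i) {
    daily_tbl(c("A", "B"), dates[i], mean_column = c(i, i))
  }))
  top <- select_polluted_days(daily, fraction = 0.05)
  expect_identical(top, dates[96:100])                     # 5 largest of 100

  # tie at the selection boundary: the earlier date wins
  vals <- c(rep(1, 96), 9, 9, 9, 9)
  vals[50] <- 9                                            # fifth nine, early
  daily2 <- dplyr::bind_rows(lapply(seq_along(dates), function(i) {
    daily_tbl("A", dates[i], mean_column = vals[i])
  }))
  top2 <- suppressWarnings(select_polluted_days(daily2, fraction = 0.04))
  expect_identical(top2, sort(dates[c(50, 97, 98, 99)]))

  # a day below the coverage rule is never selected
  daily3 <- dplyr::bind_rows(
    daily_tbl(c("A", "B"), "2021-01-01", c(10, NA)),       # 50% coverage: valid
    daily_tbl(c("A", "B"), "2021-01-02", c(NA, NA)),       # invalid
    daily_tbl(c("A", "B"), "2021-01-03", c(1, 1)))
  top3 <- suppressWarnings(select_polluted_days(daily3, fraction = 0.5))
  expect_identical(top3, as.Date("2021-01-01"))
  expect_warning(select_polluted_days(daily3, fraction = 0.5), "valid days")
})

test_that("normalized gradient maps the regional maximum to one", {
  expect_equal(unname(normalized_gradient(c(a = 3, b = 3))), c(1, 1))
  expect_equal(normalized_gradient(c(a = 2, b = 8))[["a"]], 0.25)
  expect_equal(unname(normalized_gradient(c(solo = 4))), 1)
  expect_length(normalized_gradient(c(a = NA_real_)), 0)
})

test_that("group separation drives the disparity sign and size", {
  dates <- as.Date("2021-01-01") + 0:29
  # white wholly in polygon A (value 2), minority wholly in B (value 3)
  daily <- dplyr::bind_rows(lapply(dates, function(d) {
    daily_tbl(c("A", "B"), d, mean_column = c(2, 3))
  }))
  demo <- tibble::tibble(
    geoid = c("A", "B"),
    white = c(1000, 0), hispanic = c(0, 500), black = c(0, 300),
    asian = c(0, 150), native_american = c(0, 50),
    income_below_124 = c(0, 600), income_above_150 = c(900, 0))
  rmap <- tibble::tibble(geoid = c("A", "B"), region_id = "R1")
  rep <- quiet(disparity_report(daily, demo, rmap))
  full <- rep[rep$window == "full", ]
  expect_equal(full$race_disparity_pct, 50)
  expect_equal(full$income_disparity_pct, 50)

  # identical spatial distributions: zero disparity regardless of the field
  demo0 <- tibble::tibble(
    geoid = c("A", "B"), white = c(700, 350), hispanic = c(150, 75),
    black = c(90, 45), asian = c(45, 22.5), native_american = c(15, 7.5),
    income_below_124 = c(250, 125), income_above_150 = c(650, 325))
  rep0 <- quiet(disparity_report(daily, demo0, rmap))
  expect_equal(rep0$race_disparity_pct, c(0, 0), tolerance = 1e-12)
  expect_equal(rep0$income_disparity_pct, c(0, 0), tolerance = 1e-12)
})

test_that("relative disparity is invariant to scale and row order", {
  dates <- as.Date("2021-01-01") + 0:24
  set.seed(31)
  vals <- matrix(runif(4 * 25, 1, 6), nrow = 4)
  daily <- dplyr::bind_rows(lapply(seq_along(dates), function(i) {
    daily_tbl(c("A", "B", "C", "D"), dates[i], mean_column = vals[, i])
  }))
  demo <- tibble::tibble(
    geoid = c("A", "B", "C", "D"),
    white = c(800, 100, 300, 50), hispanic = c(50, 400, 100, 20),
    black = c(30, 200, 80, 10), asian = c(15, 80, 40, 5),
    native_american = c(5, 20, 10, 58),
    income_below_124 = c(100, 500, 150, 30),
    income_above_150 = c(700, 100, 250, 40))
  rmap <- tibble::tibble(geoid = c("A", "B", "C", "D"), region_id = "R1")
  base <- quiet(disparity_report(daily, demo, rmap))

  scaled <- daily; scaled$mean_column <- scaled$mean_column * 7.3
  rep_s <- quiet(disparity_report(scaled, demo, rmap))
  expect_equal(rep_s$race_disparity_pct, base$race_disparity_pct,
               tolerance = 1e-9)
  expect_equal(rep_s$income_disparity_pct, base$income_disparity_pct,
               tolerance = 1e-9)

  perm <- daily[sample(nrow(daily)), ]
  rep_p <- quiet(disparity_report(perm, demo[sample(4), ], rmap[sample(4), ]))
  expect_equal(rep_p$race_disparity_pct, base$race_disparity_pct,
               tolerance = 1e-12)
})

test_that("regions without demographic coverage are skipped with a message", {
  daily <- daily_tbl(c("A", "B"), "2021-01-01", c(1, 2))
  demo <- tibble::tibble(geoid = "A", white = 10, hispanic = 1, black = 1,
                         asian = 1, native_american = 1,
                         income_below_124 = 2, income_above_150 = 8)
  rmap <- tibble::tibble(geoid = c("A", "B"), region_id = c("R1", "R2"))
  expect_message(
    rep <- suppressWarnings(disparity_report(daily, demo, rmap)),
    "no demographic coverage")
  expect_identical(unique(rep$region_id), "R1")
})

test_that("tidy and glance summarise the report", {
  dates <- as.Date("2021-01-01") + 0:24
  daily <- dplyr::bind_rows(lapply(dates, function(d) {
    daily_tbl(c("A", "B"), d, mean_column = c(2, 3))
  }))
  demo <- tibble::tibble(
    geoid = c("A", "B"), white = c(1000, 0), hispanic = c(0, 500),
    black = c(0, 300), asian = c(0, 150), native_american = c(0, 50),
    income_below_124 = c(0, 600), income_above_150 = c(900, 0))
  rmap <- tibble::tibble(geoid = c("A", "B"), region_id = "R1")
  rep <- quiet(disparity_report(daily, demo, rmap))
  td <- tidy(rep)
  expect_setequal(td$dimension, c("race", "income"))
  expect_equal(td$disparity_pct[td$dimension == "race" & td$window == "full"],
               50)
  gl <- glance(rep)
  expect_identical(gl$n_regions, 1L)
  expect_equal(gl$frac_race_positive, 1)
  p <- autoplot(rep)
  expect_s3_class(p, "ggplot")
})
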