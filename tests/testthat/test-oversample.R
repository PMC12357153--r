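test_that("qa screening keeps strictly greater values only", {
  obs <- dplyr::bind_rows(
    make_pixel(qa = 0.5, id = "a"),
    make_pixel(qa = 0.75, id = "b"),
    make_pixel(qa = 0.8, id = "c"))
  kept <- quiet(screen_qa(obs, 0.75))
  expect_identical(kept$id, "c")
  expect_identical(nrow(quiet(screen_qa(obs[0, ], 0.75))), 0L)
  expect_identical(nrow(quiet(screen_qa(obs, 0))), 3L)   # all qa > 0
})

test_that("polygon means are the weighted means of contributing values", {
  # one polygon, two coincident footprints with values 1 and 3: equal
  # weights by construction, mean 2 for both schemes
  polys <- poly_tbl(rect_km(0, 0, 2, 2), geoid = "P1")
  obs <- dplyr::bind_rows(
    make_pixel(value = 1, id = "a"),
    make_pixel(value = 3, id = "b"))
  res <- oversample_polygons(obs, polys, method = c("pgo", "awo"))
  expect_equal(res$mean_column, c(2, 2), tolerance = 1e-12)
  expect_identical(res$n_obs, c(2L, 2L))

  # overlap areas in ratio 1:3 -> (1*1 + 3*3) / 4 = 2.5
  polys2 <- poly_tbl(rect_km(0, 0, 4, 1), geoid = "P1")  # 4 km E-W x 1 km
  obs2 <- dplyr::bind_rows(
    make_pixel(lon = -1.5 / KM_DEG, fwhm_x = 2, fwhm_y = 1, value = 1, id = "a"),
    make_pixel(lon = 0.5 / KM_DEG, fwhm_x = 2, fwhm_y = 3, value = 3, id = "b"))
  res2 <- oversample_polygons(obs2, polys2, method = "awo")
  expect_equal(res2$mean_column, 2.5, tolerance = 1e-9)
  expect_equal(res2$total_weight, 4, tolerance = 1e-6)
})

test_that("weighted means are bounded by contributing values", {
  cfg <- scene_config(n_days = 3, n_polygons = 30, seed = 5)
  scene <- simulate_scene(cfg)
  obs <- quiet(screen_qa(scene$observations))
  res <- oversample_polygons(obs, scene$polygons, method = c("pgo", "awo"))
  ok <- !is.na(res$mean_column)
  expect_true(all(res$mean_column[ok] >= min(obs$value) - 1e-9))
  expect_true(all(res$mean_column[ok] <= max(obs$value) + 1e-9))
})

test_that("full-window aggregation equals recombined daily windows", {
  cfg <- scene_config(n_days = 5, n_polygons = 25, seed = 3)
  scene <- simulate_scene(cfg)
  obs <- quiet(screen_qa(scene$observations))
  full <- oversample_polygons(obs, scene$polygons, method = "pgo")
  daily <- oversample_polygons(obs, scene$polygons, method = "pgo",
                               window = "daily")
  rec <- daily |>
    dplyr::group_by(geoid) |>
    dplyr::summarise(mean_column = sum(mean_column * total_weight,
                                       na.rm = TRUE) /
                                   sum(total_weight[!is.na(mean_column)]))
  cmp <- dplyr::inner_join(full, rec, by = "geoid")
  expect_equal(cmp$mean_column.x, cmp$mean_column.y, tolerance = 1e-12)
})

test_that("degenerate inputs are handled", {
  polys <- poly_tbl(rect_km(0, 0, 2, 2), geoid = "P1")
  obs <- make_pixel()
  # no observations: every polygon missing
  empty <- oversample_polygons(obs[0, ], polys, method = c("pgo", "awo"))
  expect_true(all(is.na(empty$mean_column)))
  expect_identical(empty$n_obs, c(0L, 0L))
  # no polygons: empty result
  expect_identical(nrow(oversample_polygons(obs, polys[0, ])), 0L)
  # duplicate geoids rejected
  dup <- dplyr::bind_rows(polys, polys)
  expect_error(oversample_polygons(obs, dup), "duplicate")
})

test_that("grid oversampling reproduces exact cell-share arithmetic", {
  # one footprint exactly covering a 2 x 2 block of 0.01 deg cells
  px <- make_pixel(lon = 0.01, lat = 0.01, fwhm_x = 0.02 * KM_DEG,
                   fwhm_y = 0.02 * KM_DEG, value = 4.2)
  g <- oversample_grid(px, grid_res = 0.01)
  expect_identical(nrow(g), 4L)
  expect_equal(g$mean_column, rep(4.2, 4), tolerance = 1e-12)

  # two footprints covering one cell in area ratio 3:1 -> (3*2 + 1*6)/4 = 3
  pa <- make_pixel(lon = 0.00375, lat = 0.005, fwhm_x = 0.01 * KM_DEG,
                   fwhm_y = 0.0075 * KM_DEG, value = 2, id = "a")
  pb <- make_pixel(lon = 0.00875, lat = 0.005, fwhm_x = 0.01 * KM_DEG,
                   fwhm_y = 0.0025 * KM_DEG, value = 6, id = "b")
  g2 <- oversample_grid(dplyr::bind_rows(pa, pb), grid_res = 0.01,
                        bbox = c(0, 0, 0.01, 0.01))
  expect_identical(nrow(g2), 1L)
  expect_equal(g2$mean_column, 3, tolerance = 1e-9)
})

test_that("grid values transfer to polygons by the size-dependent rule", {
  # two cells valued 1 and 3
  pa <- make_pixel(lon = 0.005, lat = 0.005, fwhm_x = 0.01 * KM_DEG,
                   fwhm_y = 0.01 * KM_DEG, value = 1, id = "a")
  pb <- make_pixel(lon = 0.015, lat = 0.005, fwhm_x = 0.01 * KM_DEG,
                   fwhm_y = 0.01 * KM_DEG, value = 3, id = "b")
  g <- oversample_grid(dplyr::bind_rows(pa, pb), grid_res = 0.01,
                       bbox = c(0, 0, 0.02, 0.01))
  # large polygon containing both cell centres: unweighted mean = 2
  big <- poly_tbl(rect_lonlat(-0.001, -0.001, 0.021, 0.011), geoid = "BIG")
  res_big <- grid_to_polygons(g, big)
  expect_equal(res_big$mean_column, 2, tolerance = 1e-6)
  # tiny polygon inside the second cell: that cell's value
  tiny <- poly_tbl(rect_lonlat(0.014, 0.004, 0.016, 0.006), geoid = "TINY")
  expect_equal(grid_to_polygons(g, tiny)$mean_column, 3, tolerance = 1e-6)
  # tiny polygon equidistant between the two centres: lower cell index wins
  mid <- poly_tbl(rect_lonlat(0.0095, 0.004, 0.0105, 0.006), geoid = "MID")
  expect_equal(grid_to_polygons(g, mid)$mean_column, 1, tolerance = 1e-6)
})

test_that("gaussian tails fill polygons that area overlap leaves missing", {
  # 3 x 3 footprints tiling [0, 0.15] deg; the centre footprint is cloudy.
  # one polygon sits wholly inside the centre footprint.
  step <- 0.05
  obs <- dplyr::bind_rows(lapply(0:8, function(k) {
    i <- k %% 3; j <- k %/% 3
    make_pixel(lon = step / 2 + i * step, lat = step / 2 + j * step,
               fwhm_x = step * KM_DEG, fwhm_y = step * KM_DEG,
               value = 2, qa = if (k == 4) 0.5 else 0.95,
               id = paste0("p", k))
  }))
  polys <- poly_tbl(
    rect_lonlat(0.07, 0.07, 0.08, 0.08),    # wholly inside centre footprint
    rect_lonlat(0.01, 0.01, 0.04, 0.04),    # inside a clear footprint
    geoid = c("IN_CLOUD", "CLEAR"))
  kept <- quiet(screen_qa(obs))
  res <- oversample_polygons(kept, polys, method = c("pgo", "awo"))
  miss <- count_missing(res)
  expect_identical(miss$n_missing[miss$method == "awo"], 1L)
  expect_identical(miss$n_missing[miss$method == "pgo"], 0L)
  expect_lt(miss$n_missing[miss$method == "pgo"],
            miss$n_missing[miss$method == "awo"])
  # the tail-filled value still equals the (constant) field
  pgo_in <- res[res$method == "pgo" & res$geoid == "IN_CLOUD", ]
  expect_equal(pgo_in$mean_column, 2, tolerance = 1e-9)
})
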