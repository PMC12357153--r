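test_that("generators are deterministic under the scene seed", {
  cfg <- scene_config(n_days = 3, n_polygons = 20, seed = 17)
  f1 <- generate_field(cfg, 2)(c(-99.7, -99.2), c(40.1, 39.6))
  f2 <- generate_field(cfg, 2)(c(-99.7, -99.2), c(40.1, 39.6))
  expect_identical(f1, f2)
  expect_false(identical(
    f1, generate_field(scene_config(n_days = 3, seed = 18), 2)(
      c(-99.7, -99.2), c(40.1, 39.6))))

  s1 <- generate_swath(cfg, 1); s2 <- generate_swath(cfg, 1)
  expect_identical(s1, s2)
  p1 <- generate_polygons(cfg); p2 <- generate_polygons(cfg)
  expect_identical(p1$geometry, p2$geometry)
  expect_identical(generate_demographics(p1, cfg),
                   generate_demographics(p2, cfg))
})

test_that("the field is plumes over background with daily modulation", {
  cfg <- scene_config(daily_sigma = 0, n_days = 10,
                      plumes = data.frame(lon = -99.7, lat = 40.1,
                                          amplitude = 8, decay_km = 12))
  f <- generate_field(cfg, 3)
  expect_equal(f(-99.7, 40.1), 1 + 8)            # centre: background + amp
  expect_gt(f(-99.7, 40.1), f(-99.6, 40.1))      # decays away from the core
  # zero plumes: constant background
  cfg0 <- scene_config(daily_sigma = 0,
                       plumes = data.frame(lon = numeric(0), lat = numeric(0),
                                           amplitude = numeric(0),
                                           decay_km = numeric(0)))
  f0 <- generate_field(cfg0, 1)
  expect_equal(f0(c(-99.9, -99.1), c(39.6, 40.4)), c(1, 1))
})

test_that("swaths tile the domain with across-track growth and cloud gaps", {
  cfg <- scene_config(n_days = 1, cloud_fraction = 0, daily_sigma = 0)
  sw <- generate_swath(cfg, 1)
  expect_true(all(sw$qa > 0.75))                 # no clouds
  # constant field: every pixel value equals the constant
  cfg0 <- scene_config(cloud_fraction = 0, daily_sigma = 0,
                       plumes = data.frame(lon = numeric(0), lat = numeric(0),
                                           amplitude = numeric(0),
                                           decay_km = numeric(0)))
  sw0 <- generate_swath(cfg0, 1)
  expect_equal(sw0$value, rep(1, nrow(sw0)), tolerance = 1e-12)

  # across-track width at the swath edge vs nadir reads back as the growth
  # factor (within 2%); widths come from the corner-derived FWHMs
  fr <- swathover:::pixel_frame_table(sw)
  expect_equal(max(fr$fwhm_y) / min(fr$fwhm_y), cfg$growth_factor,
               tolerance = 0.02)
  expect_equal(min(fr$fwhm_y), cfg$pixel_across_km, tolerance = 0.02)
  # along-track extent is nominal to projection consistency (~0.2%)
  expect_lt(max(abs(fr$fwhm_x - cfg$pixel_along_km)) / cfg$pixel_along_km,
            0.002)

  # cloudy scenes put the target share of pixels below the qa threshold
  cfgc <- scene_config(cloud_fraction = 0.3)
  swc <- generate_swath(cfgc, 1)
  expect_gte(mean(swc$qa <= 0.75), 0.29)
  expect_lt(mean(swc$qa <= 0.75), 0.6)           # contiguous blobs overshoot a bit
})

test_that("polygon tessellation partitions the domain, dense near plumes", {
  cfg <- scene_config(n_polygons = 4, density_amplitude = c(0, 0))
  p4 <- generate_polygons(cfg)
  domain_area <- swathover:::geometry_area_km2(
    rect_lonlat(cfg$bbox[1], cfg$bbox[2], cfg$bbox[3], cfg$bbox[4]))
  expect_identical(nrow(p4), 4L)
  # exact partition: shoelace areas in degree space sum to the 1 x 1 domain
  deg_area <- vapply(p4$geometry, function(g)
    abs(swathover:::ring_area_signed(g[[1]][[1]])), numeric(1))
  expect_equal(sum(deg_area), 1, tolerance = 1e-9)
  expect_equal(sum(p4$area_km2), domain_area, tolerance = 1e-4)

  cfg200 <- scene_config()
  p200 <- generate_polygons(cfg200)
  # per-polygon areas use cos(latitude) at each centroid, so the sum drifts
  # from the single-latitude domain area at the 1e-5 level over 1 degree
  expect_equal(sum(p200$area_km2), domain_area, tolerance = 1e-4)
  expect_setequal(unique(p200$region_id), c("R1", "R2", "R3", "R4"))
  # urban cells near the plumes are smaller than rural ones
  km <- swathover:::domain_km(cfg200, p200$centroid_lon, p200$centroid_lat)
  pk <- swathover:::domain_km(cfg200, cfg200$plumes$lon[1], cfg200$plumes$lat[1])
  d1 <- sqrt((km[, 1] - pk[1])^2 + (km[, 2] - pk[2])^2)
  expect_lt(median(p200$area_km2[d1 < 10]), median(p200$area_km2[d1 > 30]))
  expect_lt(min(p200$area_km2), 0.1)             # downtown-scale cells exist
})

test_that("demographic segregation behaves as constructed", {
  cfg1 <- scene_config(segregation = 1, income_segregation = 1,
                       plumes = data.frame(lon = -99.7, lat = 40.1,
                                           amplitude = 8, decay_km = 12))
  polys <- generate_polygons(cfg1)
  demo1 <- generate_demographics(polys, cfg1)
  minority <- rowSums(demo1[, c("hispanic", "black", "asian",
                                "native_american")])
  share <- minority / (minority + demo1$white)
  km <- swathover:::domain_km(cfg1, polys$centroid_lon, polys$centroid_lat)
  pk <- swathover:::domain_km(cfg1, -99.7, 40.1)
  d <- sqrt((km[, 1] - pk[1])^2 + (km[, 2] - pk[2])^2)
  expect_equal(share[which.min(d)], max(share))      # maximal at the core
  # population density scales as 1/area
  pop <- demo1$white + minority
  expect_equal(stats::cor(pop, 1 / polys$area_km2), 1, tolerance = 1e-9)

  # s = 0: identical shares everywhere
  cfg0 <- scene_config(segregation = 0, income_segregation = 0)
  demo0 <- generate_demographics(polys, cfg0)
  share0 <- rowSums(demo0[, c("hispanic", "black", "asian",
                              "native_american")]) /
            (demo0$white + rowSums(demo0[, c("hispanic", "black", "asian",
                                             "native_american")]))
  expect_equal(max(share0) - min(share0), 0, tolerance = 1e-12)
})

test_that("stagnation days lead the daily ranking when variability is low", {
  cfg <- scene_config(n_days = 40, daily_sigma = 0.02, cloud_fraction = 0,
                      stagnation_fraction = 0.1, sharpening = 2)
  stag <- stagnation_days(cfg)
  # regional means the way the pipeline sees them: over polygon centroids,
  # which cluster near the plume cores where sharpening raises the field
  polys <- generate_polygons(cfg)
  means <- vapply(seq_len(cfg$n_days), function(d) {
    f <- generate_field(cfg, d)
    mean(f(polys$centroid_lon, polys$centroid_lat))
  }, numeric(1))
  expect_true(all(stag %in% order(-means)[seq_along(stag)]))
})
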