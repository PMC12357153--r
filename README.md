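# swathover

Satellite trace-gas columns (for example tropospheric NO₂ from a push-broom
imaging spectrometer, in units of 10¹⁵ molecules/cm²) come as Level-2
swaths: one irregular quadrilateral footprint per retrieval, a different
geometry every overpass. Health and environmental-justice work, on the
other hand, lives on administrative polygons — census block groups keyed by
GEOID, with demographic tables attached. `swathover` aggregates the swaths
**directly onto the polygons**, skipping the usual detour through a regular
Level-3 grid, and then computes population-weighted exposure-disparity
statistics on the result. It is written for researchers linking satellite
air-quality retrievals with socioeconomic or health data at neighborhood
scale.

## The method

Each footprint *i* with column Ωᵢ contributes to polygon *x* with a weight
*w*ᵢ,ₓ, and the average over a temporal window *t* is the weighted mean

    mean(x, t) = Σₜ Σᵢ wᵢ,ₓ Ωᵢ / Σₜ Σᵢ wᵢ,ₓ

Two weighting schemes are implemented:

* **PGO** (physics-based Gaussian oversampling): the instrument is more
  sensitive at the centre of its field of view than at the edge, so the
  footprint is modelled as a 2-D super-Gaussian spatial response

      S(x, y) = exp(−(|x/wₓ|ⁿ + |y/w_y|ᵐ)),
      wₓ = FWHMₓ / (2 (ln 2)^{1/n}),   w_y = FWHM_y / (2 (ln 2)^{1/m})

  with x, y the along-/across-track distances from the footprint centre,
  the FWHMs the corner-derived footprint extents, and exponents n = 2,
  m = 4 for a push-broom imager. The weight is the integral of S over the
  polygon, evaluated on a 10 × 10 raster of the polygon's bounding box.
  Because S never reaches zero, polygons under a cloud-masked footprint
  still receive weight from surrounding valid pixels.

* **AWO** (area-weighted oversampling): the classical scheme — the weight
  is the overlap area between the footprint quadrilateral and the polygon.

A third route, **AWO-Grid**, reproduces the conventional baseline:
area-weighted averaging onto a regular 0.01° grid, then assignment of grid
cells to polygons (cell-centre mean for polygons larger than a cell,
nearest cell to the centroid for smaller ones).

The disparity layer computes, per region (CBSA-like grouping), the
population-weighted mean exposure of demographic groups — white
non-Hispanic versus pooled minority (Hispanic, Black, Asian, Native
American), and low income (income-to-poverty ratio < 1.24) versus high
(> 1.5) — and the relative disparity 100 × (comparison − reference) /
reference, both over the full record and over the top 5 % most polluted
days ranked by regional daily mean.

Everything runs offline: a seeded synthetic-scene generator produces
push-broom swaths with across-track footprint growth, contiguous cloud
gaps, plume-plus-background column fields with stagnation-day sharpening,
density-adaptive polygon tessellations, and demographics with tunable
residential segregation.

## Worked example

```r
library(swathover)
library(dplyr)

cfg   <- scene_config(n_days = 30, n_polygons = 80, seed = 42)
scene <- simulate_scene(cfg)
obs   <- screen_qa(scene$observations)          # QA > 0.75
#> screen_qa: kept 11315 of 14520 observations (qa > 0.75)

res <- oversample_polygons(obs, scene$polygons, method = c("pgo", "awo"))
res |> group_by(method) |> summarise(
  min = min(mean_column, na.rm = TRUE), median = median(mean_column, na.rm = TRUE),
  max = max(mean_column, na.rm = TRUE), n_missing = sum(is.na(mean_column)))
#>   method   min median   max n_missing
#> 1 awo     1.16   3.96  7.99         0
#> 2 pgo     1.16   3.95  7.79         0
```

The two schemes agree closely on the 30-day average (medians 3.95 vs 3.96,
in 10¹⁵ molecules/cm²); the range spans the rural background (~1.2) to the
plume cores (~8). Daily windows feed the disparity layer:

```r
daily <- oversample_polygons(obs, scene$polygons, method = "pgo",
                             window = "daily")
rep <- disparity_report(daily, scene$demographics, scene$region_map)
rep[, c("region_id", "window", "exposure", "race_disparity_pct")]
#>   region_id   window exposure race_disparity_pct
#> 1        R1     full     7.72              0.388
#> 2        R1 top-days    14.12              0.393
#> 3        R2     full     1.95              4.088
#> 4        R2 top-days     3.73              4.787
#> ...
glance(rep)
#>   n_regions frac_race_positive frac_income_positive frac_race_increase_top_days
#> 1         4                  1                    1                        0.75
```

Every region shows the minority group more exposed (positive disparity,
because the generator concentrates minority populations near the plume
cores with segregation 0.5), and in 3 of 4 regions the disparity is larger
on the most polluted days, where stagnation sharpens the plumes. `tidy()`
gives the report in long form and `autoplot()` draws it; `plot_polygon_means()`
maps a result.

A command-line wrapper covers the same pipeline
(`inst/scripts/swathover simulate|oversample|disparity ...`), writing CSV/
GeoJSON outputs plus a JSON run manifest that records the full resolved
configuration.

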