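---
title: "Oversampling satellite column swaths onto polygons: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oversampling satellite column swaths onto polygons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: what the two
polygon oversampling schemes and the grid baseline compute, which knobs
matter, what the synthetic scenes do and do not emulate, and where the
design was genuinely open and a choice had to be made.

## The estimation problem

A Level-2 swath product delivers one column amount per footprint — an
irregular quadrilateral whose shape changes with viewing angle — while the
quantities of interest (exposure of a census block group, disparity between
demographic groups) are defined on administrative polygons. Every scheme in
this package is a weighted mean per polygon $x$ and temporal window $t$:

$$\bar\Omega_{x,t} \;=\; \frac{\sum_t\sum_i w_{i,x}\,\Omega_i}
                              {\sum_t\sum_i w_{i,x}}$$

with $\Omega_i$ the screened column values (quality assurance strictly
greater than 0.75 by default) and $w_{i,x} \ge 0$ a geometric weight. The
denominator is always the per-polygon sum of the same weights that appear
in the numerator; this is what makes a spatially constant field come back
exactly constant (the conservation test), and it makes window recombination
exact: means over any union of windows are recovered from per-window
numerators and denominators, which the disparity layer exploits when it
averages over the most polluted days.

### Physics-based weights (PGO)

A push-broom spectrometer is not uniformly sensitive over its nominal
footprint. The spatial response is modelled as a 2-D super-Gaussian in the
pixel-local frame,

$$S(x,y)=\exp\!\left(-\left|\frac{x}{w_x}\right|^{n}
                      -\left|\frac{y}{w_y}\right|^{m}\right),
\qquad w_x=\frac{\mathrm{FWHM}_x}{2(\ln 2)^{1/n}},\quad
        w_y=\frac{\mathrm{FWHM}_y}{2(\ln 2)^{1/m}},$$

where $x$ is along-track, $y$ across-track, and the logarithm is natural —
forced, not conventional: only $\ln$ makes $S(\pm\mathrm{FWHM}_x/2,0)=1/2$,
which the test suite asserts to $10^{-12}$ for $n,m \in \{1,2,4,8\}$. The
defaults $n=2$ (along) and $m=4$ (across) give the flatter-topped
across-track profile characteristic of a push-broom imager; both are
arguments of `oversample_polygons()`.

The weight is the integral of $S$ over the polygon. Following the
rasterization approach, each polygon (each part of a multipolygon) is
covered by a 10 × 10 grid over its bounding box. One deliberate deviation
from the simplest rule is made here: a cell contributes
$S(\text{centre}) \times \text{area}(\text{cell} \cap \text{polygon})$,
with the intersection computed exactly by convex clipping, rather than
"full cell area if the centre is inside, else nothing". The binary rule
carries boundary-indicator noise of roughly 4 % (one sigma) for
kilometre-scale convex polygons at resolution 10 — measured against a
400 × 400 midpoint-quadrature oracle — and that noise alone breaches the
5 % oracle-equivalence bound the package holds itself to. Coverage
weighting removes the indicator noise (max oracle error observed: 1.1 %)
while keeping the raster structure and the same continuum limit. A useful
side effect is that the covered cell areas sum exactly to the polygon
area, which the tests assert.

Two numerical notes. First, $S$ is strictly positive in exact arithmetic,
but with $m=4$ the across-track tail underflows double precision beyond
about $5w_y$; this is irrelevant in practice (weights $<10^{-300}$) but
means "strictly positive at any finite distance" holds only along-track in
floating point. Second, candidate footprints for a polygon are truncated at
a bounding-box dilation of 3 × max(FWHM) (configurable), where the response
is below $10^{-4}$ of its peak.

### Area weights (AWO) and the grid baseline (AWO-Grid)

The classical weight is the overlap area between footprint quadrilateral
and polygon. Footprints are convex, so Sutherland–Hodgman clipping of each
polygon ring against the quadrilateral is exact; holes subtract. The grid
baseline first area-weights footprints onto a regular 0.01° grid — with an
explicit, logged registration origin, because shifting the grid shifts the
resulting spatial pattern — and then transfers cells to polygons: polygons
larger than a cell take the unweighted mean of valid cells whose centres
fall inside; smaller polygons take the cell nearest their centroid, ties
broken to the lower (row, column) index, and inherit that cell's
missingness.

### Missingness

Accumulated weight below a floor marks a polygon missing: $10^{-6} \times$
polygon area for PGO (the Gaussian tail makes the sum never exactly zero,
so a pure zero test would never fire) and $10^{-6}$ km² of overlap for AWO.
Under a contiguous cloud mask the two schemes part ways: AWO leaves
polygons wholly inside a masked footprint missing, while PGO fills them
from surrounding valid footprints — the tests construct exactly this
fixture and assert the strict ordering of missing counts, and that the
filled value is unbiased on a constant field.

## Local geometry

All distances use a per-pixel equirectangular tangent plane: 1° latitude =
111.195 km, 1° longitude = 111.195 km × cos(latitude). At footprint scale
the error against spherical geodesics is below 0.2 % (asserted against an
independent great-circle oracle), and because weights enter ratio-wise most
of it cancels. Ellipsoidal corrections (up to ~0.5 % at the equator) are
out of scope. Footprint corners are normalised on ingest to a fixed order —
corner 1 in the (−along, −across) quadrant, corners 1–2 the trailing
across-track edge — so corner roles, not formats, carry the geometry. A
centro-symmetric footprint admits two such orderings (along and −along);
the tie resolves to the north-, then east-pointing along axis. The FWHMs
are the corner-derived footprint extents (distance between across-track
edge midpoints along-track, and vice versa); whether real instruments'
calibrated response widths differ from the corner extents is instrument
knowledge the package does not presume, so `fwhm_scale` exposes a
multiplicative correction, default 1.

Antimeridian-crossing and polar (|lat| ≥ 85°) footprints are rejected
outright rather than handled approximately.

## The disparity layer

Group exposure is the population-weighted mean of polygon values —
polygons with a missing value drop out of numerator and denominator — and
disparity is the percent difference of the comparison group (pooled
minority, or low-income) from the reference (white non-Hispanic, or
high-income). Pooling the minority populations into a single comparison
group (rather than averaging per-group disparities) is deliberate: it
matches the one-population-versus-another definition. The income contrast
uses the two tails of the income-to-poverty distribution (< 1.24 vs
> 1.5); the middle band belongs to neither group.

Polluted days are the top fraction (default 5 %) of valid days ranked by
the regional daily mean, where a day is valid only if at least half the
region's polygons are non-missing — without the coverage rule, cloud-biased
days with a few clear urban polygons would dominate the ranking. The
regional mean is unweighted over non-missing polygons; whether it should be
population-weighted is not settled usage, so the unweighted form is the
default and both the coverage threshold and the fraction are arguments.
Disparity changes between windows are reported in percentage points
(top-days percent minus full-window percent). Relative disparities are
scale-invariant by construction — multiplying every polygon value by a
positive constant changes nothing — and the tests assert this along with
permutation invariance and exact zero under identical group distributions.

## What the synthetic scenes emulate — and what they do not

The generator exists so that every stage runs and is testable offline. Its
defaults are the package's reference study conditions: a 1° × 1° domain,
300 daily overpasses, two exponential plumes (amplitudes 8 and 5 × 10¹⁵
molecules/cm², decay lengths 12 and 8 km) over a background of 1, a
mean-one lognormal day factor (σ = 0.3), 20 % cloud cover in contiguous
blobs, nadir footprints of 5.5 × 3.5 km growing across-track by a factor
of 2 toward the swath edge along a 5° azimuth, ~200 polygons, and
segregation 0.5. On designated stagnation days (5 % of days) plume
amplitudes multiply and decay lengths divide by the sharpening factor
(1.8), mimicking the shallow-boundary-layer accumulation that sharpens
urban gradients on the most polluted days.

The tessellation is a seeded, density-driven recursive rectangle
partition: the leaf with the largest splitting mass (a broad plus a sharp
exponential of distance to the nearest plume core, integrated over the
leaf) splits across its longer side at a jittered fraction until the
target count is reached. This was chosen over a centroidal (Voronoi-style)
tessellation because it partitions the domain exactly by construction, is
trivially deterministic, and concentrates cells near the cores — the
generated spectrum spans ~0.06 to ~700 km² with about a third of cells
under 1 km², matching the urban block-group regime where polygon-level
methods matter. Demographics put minority share
$(1-s)\,\text{base} + s\,e^{-d/L}$ at distance $d$ from the nearest core,
so $s=0$ yields exactly uniform composition (and provably zero disparity
downstream) while $s=1$ concentrates minority populations on the cores;
population density scales as 1/area.

What passing tests on these scenes **does not** show: real retrievals have
correlated noise, striping, and QA structure tied to clouds and albedo
rather than geometric blobs; real block groups are non-convex, multi-part,
and hole-ridden where the generator's are rectangles (the geometry code
handles the general case and is tested on it, but the end-to-end scenes do
not exercise it); real plumes advect with wind rather than breathing in
place; and real segregation is not a radial function of distance to an
emission source. The convergence number the acceptance script reports
(median PGO–AWO relative difference ≈ 0.8–1.1 % across seeds on 300-day
averages) is therefore a statement about the method pair under these
conditions, not a measurement of any real product.

## Problem sizes and runtime

The reference scene is ~145 000 footprints over 200 polygons; both polygon
schemes run together in about a minute on one CPU, the full test suite in
under two minutes, and the acceptance script in about 1.5 minutes. The
constructed-city disparity sweep uses 40 days × 120 polygons with day
factor σ = 0.05 — small enough that stagnation days lead the daily ranking,
which is the regime the polluted-day selection property is stated for.

## Known limitations

* Flat-table (CSV) swath input and GeoJSON polygons only; NetCDF swaths
  and ESRI Shapefiles are not read in this build.
* Equirectangular local geometry throughout; no ellipsoidal distances,
  terrain or parallax handling.
* The QA screen is the single scalar threshold; no cloud-fraction-based
  partial screening, destriping or bias correction.
* No minimum-observation cutoff is imposed on reported means; users filter
  on the reported `total_weight` and `n_obs` instead.
* Polygon rasterization at resolution 10 is an approximation whose error
  grows for polygons much larger than a footprint with steep internal
  gradients; raise `resolution` where that matters.
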