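---
title: "Downscaled land surface temperature and heat-related elderly risk mapping"
author: "heatrisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Downscaled land surface temperature and heat-related elderly risk mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(heatrisk)
```

## The problem

Urban heat is not uniform: built-up cores run several degrees warmer than
their vegetated surroundings, day and especially night, and the people most
at risk from that excess heat — the elderly — are concentrated in exactly
those dense cores. Satellite thermal sensors observe land surface
temperature (LST) everywhere, but at a footprint (nominally 1 km) far too
coarse to resolve street-scale contrasts, while vegetation indices (NDVI)
are available at 250 m and population grids at 100 m. `heatrisk`
implements the pipeline that bridges these scales:

1. **Hazard** — statistically downscale coarse summer LST to 100 m using
   fine NDVI as the predictor, with one regression per land-cover class;
2. **Exposure** — the 100-m total-population grid;
3. **Vulnerability** — the elderly (≥ 65) population, obtained by scaling
   each pixel's population by its municipality's elderly fraction;
4. **Risk** — normalize the three layers, combine them with equal weights
   into the Heat-related Elderly Risk Index (HERI), split into five levels,
   and summarize each level's temperature, area and population.

## The downscaling model

Warm-season LST and NDVI are negatively related: vegetated surfaces are
cooler through evapotranspiration and shading. The relation differs by
surface type, so the pipeline is *nested by land-cover class*: the coarse
monthly LST and the land-cover grid are first resampled (nearest
neighbour) to the 250-m NDVI grid, every fine cell contributes one
(NDVI, LST, class) training triple per month, and a single predictive
model per class and diurnal period is fitted by pooling all months:

* **LRM** — ordinary least squares, `LST = a + b · NDVI`. The slope `b`
  (°C per unit NDVI) is the headline coefficient and is expected to be
  negative for every class.
* **GAM** — a penalized cubic regression spline `LST = f(NDVI)`
  (`mgcv::gam`, basis `"cr"`, `k = 12`, smoothing parameter by generalized
  cross-validation). The second-derivative penalty leaves straight lines
  unpenalized, so the spline *nests* the linear model: its in-sample RMSE
  can never exceed the LRM's, and it improves strictly wherever the true
  relation is curved.

Fitted models are applied pixel-wise to each month's NDVI, the monthly
predictions are averaged May–September, and the composite is resampled to
100 m — the hazard layer. Water (land-cover code 210) is excluded
throughout.

Model quality is reported per class as R², the regression coefficient
(LRM), significance and in-sample RMSE, plus an unweighted average row
(an `nObs`-weighted average is available, since a simple mean of per-class
values and a pixel-weighted mean genuinely differ). GAM significance is
an F-test of the smooth against the intercept-only model, with effective
degrees of freedom taken from the smoother trace.

Classes with fewer than `minSamples = 30` training pairs inherit the
pooled all-classes model (flagged `fallback`); a class with zero NDVI
variance raises a degenerate-fit condition. GAM predictions outside the
fitted NDVI range use constant extrapolation (clamped to the range
endpoints) — splines are untrustworthy beyond their support.

## The risk index

Each layer is normalized to [0, 1]. The package's default is min–max,
`(x − min)/(max − min)`, because that is the only scaling that guarantees
the 0-to-1 range for any input; the literal divide-by-range variant
(`x / (max − min)`) is available as `normalizeLayer(..., method =
"range")`, but its output need not lie in [0, 1] and can then fail
classification. Normalization is per scene and per period — risk maps are
city-specific, so a city's hottest pixel defines that city's hazard
maximum. Zero-population pixels are retained (they normalize to the layer
minimum, not nodata): zero exposure is legitimate information — no people,
no risk — not missing data.

Exposure and vulnerability are averaged 50/50 into an "exposed and
vulnerable" layer, which is combined 50/50 with hazard:

HERI = 0.5 · H + 0.25 · E + 0.25 · V.

All weights are equal by design (no subjective tuning); they are
configurable in `heriConfig()` but the defaults are the method. The index
is split at 0.2/0.4/0.6/0.8 into five levels — very low (≤ 0.2), low,
moderate, high, very high (> 0.8) — with the boundary value always
belonging to the lower level.

`summarizeRisk()` reports, per level: mean ± SD of LST, coverage area as %
of the unmasked city area, total and elderly population frequency as % of
the city totals, and population densities per km² (city area counts land
pixels only, consistent with water exclusion). `aggregateCoverage()`
averages coverage percentages across (city, period) members of city
groups; applied to the shipped reference table of eleven Italian cities
(`italianCityCoverage()`), the coastal day+night means for the high and
very high levels are 11.3% and 6.0% against 8.1% and 3.3% inland.

## The synthetic scene generator

Real inputs for this analysis are satellite products and census grids;
the package instead ships a generator whose scenes have *known ground
truth*, so every stage is testable without downloads.

A scene is a 12 × 12 km city (120 × 120 cells at 100 m; shapes must be
multiples of 30 so the 300-m land-cover and 1-km LST grids tile the same
extent). Its layers emulate the real stack:

* **Land cover** (300 m): concentric rings from the built-up core
  (code 190) through cropland/mosaic (14, 20) and shrubland (130) to
  forest (50); the coastal preset adds a ~1.2-km water stripe (210) on the
  eastern edge.
* **NDVI** (250 m, monthly): per-class means (0.15 in the core to 0.65 in
  the forest belt) plus a smooth random anomaly field built from six
  cosine modes with wavelengths of 6–12 km, plus faint fine-scale texture
  (SD 0.005) and a small seasonal decline over May–September. The
  long-wavelength choice reflects how city-scale greenness varies — broad
  urban–rural gradients rather than pixel noise — and keeps each 1-km
  thermal footprint close to NDVI-homogeneous, which is what makes
  NDVI-based downscaling work on real scenes too.
* **Truth LST** (100 m): the class response applied to NDVI. Urban and
  shrubland classes respond linearly (slopes −10 and −9 °C/NDVI);
  vegetated classes respond through a saturating curve,
  `intercept − depth · tanh(NDVI/scale)`, monotone decreasing, so the
  nonlinearity the GAM is meant to capture genuinely exists. Night truth
  is day truth minus a 14 °C offset.
* **Coarse LST** (1 km, monthly): the 10 × 10 block mean of truth plus
  i.i.d. Gaussian noise — SD 1.0 °C by day, 0.4 °C by night. The smaller
  night noise encodes the steadier nocturnal surface signal and is what
  makes night-time fits more accurate than daytime ones, as observed.
* **Population** (100 m): an exponential-decay surface (e-folding 1.5 km
  from the centre) apportioned to 300,000 whole persons by largest
  remainder, so the total is conserved exactly. Five municipalities
  partition the land into contiguous nearest-seed regions; their elderly
  fractions (0.17–0.25) bracket the ~21% national elderly share.

Scenes are bit-identical for a fixed seed, and generation does not
disturb the caller's RNG stream.

What the generator does **not** emulate: real urban morphology (street
canyons, coastlines with harbours), emissivity variation, cloud gaps,
multi-year trends, or spatially correlated sensor noise. Passing tests
therefore demonstrate that the *method* recovers known structure under
realistic statistical conditions — not that any particular real city's
numbers would be reproduced.

## Numerical choices

* **Resampling** is nearest-neighbour by pixel centre; when an output
  centre is exactly equidistant between two source centres the top-left
  candidate wins, making results deterministic. Coarse-to-fine resampling
  is thus exact block replication, and fine-then-back resampling is the
  identity on unmasked pixels.
* **Temporal averaging** masks a pixel when fewer than `minValidMonths`
  (default 1) months are valid — with long multi-year composites a single
  valid month is still informative, and no stricter completeness rule is
  part of the method.
* **Masking**: nodata propagates through every operation; no operation
  invents values in masked cells. Statistics always skip `NA`.
* **Degenerate inputs**: constant layers cannot be normalized (no risk
  gradient is expressible) and raise an error rather than returning an
  arbitrary constant; classification tolerates values outside [0, 1] only
  to 10⁻⁹ (clamped), beyond which it errors.
* **Problem sizes**: the test suite and the acceptance script run on
  120 × 120-cell scenes (14,400 fine pixels, ~11,500 training pairs per
  period), where the full two-period pipeline completes in a few seconds;
  the same code scales to real city rasters unchanged.

## Design decisions

* *Pooled fits, not per-month fits*: one model per (class, period) pooling
  all months is the default — a single predictive model per class is the
  method's point, and pooling is deterministic and robust for sparse
  classes. (Per-month fitting with averaged metrics is a straightforward
  extension of `fitClassModels` but is not a configuration of the default
  pipeline.)
* *mgcv as the spline engine*: the GAM is a standard penalized regression
  spline, and `mgcv` is the canonical R implementation of exactly that
  construction (cubic spline basis, curvature penalty, GCV); the package
  adds the clamping, fallback and significance conventions around it.
* *In-sample metrics*: R²/RMSE are descriptive of fit quality on the
  scene, matching how such tables are conventionally reported; no held-out
  split is used.
* *Rome-style hybrids*: group membership for cross-city aggregation is
  data (`city`,`group` table), not geometry — the reference table counts
  Rome with the inland cities.
* *Text raster format*: grids are read and written in a plain-text
  header+rows dialect (with a CSV label sidecar for categorical layers),
  chosen so fixtures and outputs are human-readable and diffable.

## Limitations

LST is a surface, not an air, temperature; the relation between the two is
complex, and no attempt is made here to convert one into the other. The
vulnerable population is characterized by age alone — health status,
income, housing quality and air conditioning are not represented. The
equal-weight index is deliberately simple; it ranks pixels within a city
and period, and index values are not comparable across cities unless
cross-city normalization is applied deliberately.

## A complete run

```{r, eval = FALSE}
scene <- generateScene(defaultSpec("inland"))
day <- runHeatRisk(scene, "day", model = "GAM")
night <- runHeatRisk(scene, "night", model = "GAM")

day$fitReport      # per-class R2, slope, significance, RMSE
day$summary        # per-level LST, coverage, population stats
exportMap(day$levels, file.path(tempdir(), "inland_day"))
```
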