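# heatrisk

High-resolution urban heat-hazard risk mapping for the elderly: statistical
downscaling of coarse summer land surface temperature (LST) with
fine-resolution NDVI, combined with population layers into a five-level
Heat-related Elderly Risk Index (HERI).

## What it does, for whom

City health services and urban planners need *street-scale* maps of where
summer heat and vulnerable residents coincide. Satellite thermal products
resolve LST at ~1 km — far too coarse — while NDVI is available at 250 m and
European population grids at 100 m. `heatrisk` is an R package for analysts
who want to bridge those scales and turn the result into an actionable risk
map. It provides the raster plumbing (alignment, nearest-neighbour
resampling, masking, temporal compositing, text-format I/O), the
downscaling models, the risk-index construction, per-level zonal reporting,
and a synthetic city-scene generator with known ground truth so the whole
pipeline is testable without any satellite download.

## The method

**Hazard.** Coarse monthly LST (day and night) and the land-cover grid are
resampled to the 250-m NDVI grid. For each land-cover class *c* a single
pooled model is fitted over all summer months:

- Linear regression (LRM): `LST = a_c + b_c · NDVI`, with `b_c < 0`
  expected (vegetated surfaces are cooler);
- Generalized additive model (GAM): `LST = f_c(NDVI)`, a penalized cubic
  regression spline (smoothing parameter by GCV) that nests the linear fit,
  so its in-sample RMSE never exceeds the LRM's and improves strictly where
  the true relation is curved.

Each model is scored by R², regression coefficient (LRM), significance and
RMSE. Predictions are made pixel-wise per month, averaged May–September,
and delivered at 100 m. Water is excluded throughout.

**Exposure and vulnerability.** Exposure is the 100-m total-population
grid; vulnerability is the elderly (≥ 65) population, computed per pixel as
`municipal elderly fraction × pixel population`.

**Risk.** The three layers are min–max normalized to [0, 1] per city and
period and combined with equal weights,

```
HERI = 0.5·hazard + 0.25·exposure + 0.25·vulnerability,
```

then split at 0.2/0.4/0.6/0.8 into five levels (very low … very high, the
boundary always belonging to the lower level). Per level, the package
reports mean ± SD LST, coverage area (%), total/elderly population
frequency (%) and density (per km²), and can average coverage across city
groups (e.g. coastal vs inland).

## Worked example

```r
library(heatrisk)

scene <- generateScene(defaultSpec("inland"))   # 12 x 12 km synthetic city
run <- runHeatRisk(scene, "day", model = "GAM")
run$fitReport
run$summary
```

The fit report gives one row per land-cover class plus an average row
(class `NA`):

```
  class period model     r2 slope   p_value rmse n_obs fallback
1    14    day   GAM 0.4553    NA 3.45e-267 1.48  2100    FALSE
2    20    day   GAM 0.3525    NA 1.69e-311 1.29  3400    FALSE
3    50    day   GAM 0.0684    NA  1.78e-14 1.67  1260    FALSE
4   130    day   GAM 0.1480    NA 9.17e-135 1.39  4100    FALSE
5   190    day   GAM 0.2095    NA  2.91e-32 1.75   660    FALSE
6    NA    day   GAM 0.2467    NA  3.57e-15 1.51  2304       NA
```

— e.g. class 14 (cropland) explains 46% of LST variance with an in-sample
RMSE of 1.48 °C; GAM rows carry no linear slope. The level summary:

```
  level level_name mean_lst sd_lst coverage_area_pct total_pop_freq_pct
1     1   very low     25.7  0.633             34.67              19.21
2     2        low     28.5  0.915             55.33              39.39
3     3   moderate     29.5  0.392              5.05              13.23
4     4       high     31.6  0.566              3.74              18.70
5     5  very high     32.0  0.221              1.21               9.47
  elderly_pop_freq_pct total_pop_density elderly_pop_density
1                 17.8              1154                 246
2                 37.4              1483                 323
3                 14.0              5458                1330
4                 20.4             10409                2601
5                 10.3             16323                4081
```

— the very-high-risk level covers 1.2% of the city but holds 9.5% of the
population at 16,323 persons/km², with density rising monotonically across
risk levels: the index concentrates on the dense, hot urban core.
`exportMap(run$levels, "inland_day")` writes the categorical raster and a
legended PNG.

## Package layout

- `R/grids.R`, `R/grid-io.R` — raster model, resampling, compositing, I/O
- `R/synthetic.R` — scene generator (`sceneSpec()`, `generateScene()`)
- `R/downscale.R` — training table, `fitLrm()`/`fitGam()`, prediction,
  hazard layer, fit report
- `R/population.R` — exposure and vulnerability layers
- `R/heri.R` — normalization, weighted combination, classification
- `R/report.R` — zonal summaries, cross-city aggregation, map export
- `vignettes/heat-risk-mapping.Rmd` — the methods vignette
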