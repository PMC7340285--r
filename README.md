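# whalekrill

Spatial hotspot and trophic overlap modelling for baleen whales and krill.

Shipboard line-transect surveys off central California record whale
sightings, continuous krill echosounder backscatter and in-situ oceanography
along the same 3 km track bins, year after year. Turning those bins into
management-relevant maps — *where do blue whales, humpback whales and their
euphausiid prey persistently concentrate, and how strongly do predator and
prey fields overlap?* — takes a long chain of standard but fiddly steps,
each with its own failure modes. `whalekrill` implements that chain as a
tested R package for quantitative ecologists who want the machinery to be
verifiable: every stage can be run against a synthetic study system with
known ground truth, so parameter recovery, calibration of significance
procedures and map bookkeeping are all checked by the test suite rather
than trusted.

The chain:

- **Ordinary kriging** of temperature, salinity and fluorescence (surface
  1–9 m along-track; midwater 30–40 m at stations) per cruise onto a 1 km²
  grid, with variogram selection by leave-one-out RMSE and four quality
  gates (>90% of LOOCV predictions within the measured mean ± 1.96 SD and
  within ± 2 SD, %RMSE < 30, |%ME| < 2), falling back to second-order trend
  removal when a gate fails.
- **Acoustic biomass**: area backscattering coefficients apportioned over a
  length-frequency distribution, divided by per-length backscattering
  cross-sections σ_bs, multiplied by the length–weight relationship
  *M(L) = 0.0002 L² − 0.0017 L + 0.005* g (8–30 mm), binned at 3 km with
  sampled-cell volume as effort.
- **Abundance models**: a two-part hurdle for krill — logistic
  presence/absence plus zero-truncated NB2 (variance μ + μ²/θ) conditional
  on positivity, offset by log acoustic volume — and NB2 GLMs with log
  survey-area offsets for whale counts, compared against zero-inflated
  counterparts by the Vuong test. Line-transect densities
  *D = n / (2 L · ESW · g(0))*.
- **Covariate selection**: univariate screening (polynomial ladder for
  oceanographic/bathymetric variables, four transforms for distances, 0–3
  month lags for climate indices), manual-style backward stepwise
  elimination under an AIC-decrease rule, the ΔAIC-2 / BIC closing rule,
  year-interaction testing by likelihood ratio, with VIF, Moran's I,
  Nagelkerke R² and repeated 10-fold CV as diagnostics.
- **Hotspots and overlap**: per-month Getis-Ord G\*ᵢ with self-inclusive
  3 km band weights, Benjamini–Hochberg FDR masking (positive z, adjusted
  p < 0.05), masked z-scores rescaled to [0, 1] and summed into a
  persistence surface (0 to the number of modelled months), and the AB
  ratio — spatial covariance of predator and prey over the product of their
  means — globally per year and locally per cell.

## Worked example

Simulate a two-year survey on a 30 × 20 km shelf grid and fit the krill
hurdle model at the generating term basis:

```r
library(whalekrill)

grid    <- make_study_grid(c(30, 20), 1)
truth   <- default_truth_spec(seed = 1)
climate <- make_climate_table(2004:2005, seed = 1)
cruises <- make_cruises(2004:2005, c(5, 6, 7, 9), climate)
bins    <- simulate_observations(grid, cruises, truth, seed = 2)
bins$krill_present <- as.integer(bins$krill_biomass > 0)

fit_hurdle(
  design_spec("krill_present", truth$krill_presence$terms, family = "logistic"),
  design_spec("krill_biomass", truth$krill_count$terms,
              offset = "acoustic_volume", family = "ztnb"),
  bins)
```

```
<wk_hurdle> combined AIC: 5291.35  BIC: 5335.26
-- zero part --
<wk_fit> logistic  n = 400
              estimate      se      p
(Intercept)   -39.4866 18.1645 0.0297
temp_mid        8.8553  3.5897 0.0136
temp_mid_2     -0.4515  0.1767 0.0106
log_dist_200m  -0.8725  0.2751 0.0015
soi_lag0        0.3872  0.0806 0.0000
logLik: -150.99  AIC: 311.97  BIC: 331.93
-- count part --
<wk_fit> ztnb  n = 339
              estimate     se      p
(Intercept)    -8.7716 0.2827 0.0000
fluor_surf      0.7554 0.0978 0.0000
fluor_surf_2   -0.0349 0.0097 0.0003
dist_mainland  -0.0178 0.0058 0.0021
ui_lag1         0.0032 0.0007 0.0000
theta: 1.346
logLik: -2483.69  AIC: 4979.38  BIC: 5002.33
```

The 400 bins carry 15.2% krill zeros; every estimate sits within sampling
error of its generating value (zero part γ = (−46.35, 10, −0.5, −0.8,
0.35); count part β = (−8.87, 0.8, −0.04, −0.02, 0.0035), θ = 1.2). A
hotspot/overlap fragment on a constructed prey aggregation:

```r
segment_density(n = 2, L = 3, esw = 1.1, g0 = 0.9)
#> [1] 0.3367003

v  <- 10 * exp(-((grid$x - 8)^2 + (grid$y - 10)^2) / 8) + 0.3
hs <- hotspot_raster(prediction_raster(v, "krill", 2004, 6),
                     grid[, c("x", "y")], band = 3)
sum(hs$mask)                      # 76 of 600 cells flagged (max z = 21.1)
ab_ratio_global(v^0.8 + 0.1, v)   # predator tracking prey
#> [1] 2.250365
```

## The analysis workflow

`analysis/01_simulate.R` through `analysis/07_hotspots_overlap.R` run the
chain as a narrative sequence on a five-year synthetic study (20 cruises,
1,000 bins, 120 kriged surfaces), writing tables and ASCII-grid rasters
under `results/`. Each driver is a thin script over the package functions;
`run_pipeline()` executes the same chain in one call with a validated
config and a checksummed artifact manifest. The methods vignette
(`vignettes/whalekrill-methods.Rmd`) documents the models, the numerical
choices and what the synthetic system does and does not emulate.

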