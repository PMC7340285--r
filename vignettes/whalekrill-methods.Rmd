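---
title: "Methods: spatial hotspot and trophic overlap modelling for whales and krill"
author: "whalekrill"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial hotspot and trophic overlap modelling for whales and krill}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The analysis chain

`whalekrill` implements the modelling chain used to map foraging hotspots of
blue whales (*Balaenoptera musculus*) and humpback whales (*Megaptera
novaeangliae*) and their euphausiid prey (*Euphausia pacifica*,
*Thysanoessa spinifera*) from shipboard line-transect surveys:

1. **Oceanographic surfaces.** Temperature, salinity and chlorophyll-*a*
   fluorescence, measured along-track (surface, 1–9 m) and at stations
   (midwater, 30–40 m), are interpolated per cruise onto a 1 km² prediction
   grid by isotropic ordinary kriging, with leave-one-out quality gates and a
   second-order trend-removal fallback.
2. **Acoustic krill biomass.** Area backscattering coefficients are converted
   to biomass density by apportioning backscatter over a trawl-derived
   length-frequency distribution, dividing by per-length backscattering
   cross-sections, and multiplying by the length–weight relationship
   $M(L) = 0.0002L^2 - 0.0017L + 0.005$ g (L in mm, 8–30 mm span); samples
   are aggregated into 3 km track bins with summed sampled-cell volume as
   effort.
3. **Abundance models.** Krill biomass per bin is modelled with a two-part
   hurdle: logistic presence/absence and a zero-truncated NB2 count part
   conditional on positivity, offset by log acoustic volume. Whale counts per
   bin are NB2 GLMs with a log survey-area offset, checked against
   zero-inflated alternatives by the Vuong test (zero-inflation adopted only
   on significant improvement at p < 0.05 — with no structural zeros expected,
   the hurdle/NB reading is the default). Line-transect densities use
   $D_i = n_i / (2 L_i \,\mathrm{ESW}_i \, g(0)_i)$ with segment-specific
   effective strip half-width and trackline detection probability supplied as
   inputs.
4. **Covariate selection.** Univariate screening fixes each covariate's
   functional form (details below); backward stepwise elimination then prunes
   the full model under an AIC-decrease rule, the ΔAIC-2 / BIC rule picks the
   final model from the path, and year interactions for static features are
   tested by likelihood ratio.
5. **Maps, hotspots and overlap.** Final models predict to the grid at one
   effort unit; maps are averaged monthly/annually/overall (months within
   year first, then across years, weighting years equally) and scaled into
   pooled deciles. Per month, Getis-Ord $G_i^*$ identifies hotspot cells
   under Benjamini–Hochberg FDR control (positive z, adjusted p < 0.05);
   masked z-scores are rescaled to [0, 1] and summed into a persistence
   surface (0 to the number of modelled months). Trophic overlap is the AB
   ratio — spatial covariance of predator and prey fields over the product of
   their means — globally per year and locally per cell with temporal
   mean/SD maps.

Every stage is exercised end-to-end on a synthetic study system with known
ground truth (`default_truth_spec()`, `simulate_observations()`), which is
what makes the pipeline testable without survey data.

# The synthetic study system

The generator reproduces the *structure* of the survey: a small coastal
planar domain (default 30 × 20 km at 1 km² cells) with a coastline, an
island, a shallow bank and a 200 m isobath; east–west transects cut into
3 km bins (end-of-line fragments under 1 km discarded); six oceanographic
fields per cruise drawn as Gaussian random fields with exponential
covariance; monthly AR(1) climate indices (SOI, PDO, NPGO, UI) attached at
lags 0–3 months; and responses drawn from exactly the families the models
fit. Distances are plain Euclidean distances in km — the real study area is
small enough that projected geometry is the appropriate model.

Rates are calibrated to the study system being emulated: ~17% krill zeros,
~3% blue and ~16% humpback presences per bin, positive krill biomass
10²–10⁴ integer grams (the krill response is treated as count data).
Acoustic effort is cell count × a constant cell volume, mirroring how
sampled volume is recorded; ESW and g(0) come from a sea-state lookup
(detection-function estimation is out of scope and treated as supplied).

What the generator does **not** emulate: ship-track logistics and weather
gaps, a real coastline, anisotropy, tidal advection, prey patchiness below
the bin scale, and observation error in the covariates at the bins (bins
read the true fields; the kriging stage sees those values as its
measurements). Passing tests therefore demonstrate the *machinery* is
correct and well-calibrated under the stated families — not that the
families fit any particular ocean.

Truth coefficients are written on the raw covariate scale as displaced
quadratics, e.g. a blue whale thermal optimum at 13 °C with curvature
−0.08 °C⁻²; each species carries one quadratic oceanographic term, one
distance term and one lagged climate term — the smallest basis that
exercises every screening pathway.

# Kriging details

- **Variogram.** Classical semivariance estimator in 15 equal lag bins to
  half the domain diameter; weighted least squares (weights = pair counts)
  over exponential, spherical and Gaussian families with the winning family
  chosen by leave-one-out RMSE of the induced kriging predictor. Parameters
  are optimised on the log scale with bounds (sill within e³ of the
  empirical maximum, range between a quarter of the smallest and ten times
  the largest lag) — unbounded fits can run away to numerically singular
  systems. `sill` is the total sill; `range` is the exponential scale
  parameter.
- **System.** Global kriging (all points; synthetic cruises have at most a
  few hundred) in covariance form with the unbiasedness constraint.
  Coincident points (closer than 1e-6 km) share the full covariance, which
  makes kriging an exact interpolator to ~1e-8 even with a nugget; duplicate
  locations are averaged first. A diagonal ridge (escalating from 1e-10 to
  1e-4 of the sill, applied only on failure) conditions near-singular
  systems — smooth Gaussian covariances need this.
- **Leave-one-out.** Computed in closed form from the inverse of the full
  kriging system (`error_i = (A^{-1}z^*)_i / (A^{-1})_{ii}`), verified in
  tests against literal re-solving.
- **Quality gates.** More than 90% of LOOCV predictions within the measured
  mean ± 1.96 SD, more than 90% within ± 2 SD, %RMSE < 30 and |%ME| < 2.
  The paper-style thresholds come without denominators; both error metrics
  are normalised by the measured data *range*, the scale-free convention,
  and the "95% CI of the measured data" is read as the tolerance band
  mean ± 1.96 SD (a CI on the mean would be unsatisfiable for interpolated
  values). A constant field passes by convention, flagged.
- **Detrending.** One pass: fit the full second-order polynomial in (x, y)
  by least squares, krige the residuals, add the trend back; LOOCV refits
  the trend without each point. Still-failing surfaces are emitted with
  `passed = FALSE` and a warning — no iteration rule is defined for
  repeated detrending, and under global kriging the gates fail on data
  geometry (fine-scale bimodality, heavy tails) that detrending cannot
  repair, rather than on smooth trends, which global kriging already
  handles.

# Model-fitting details

- **NB2 everywhere** (variance $\mu + \mu^2/\theta$). Plain NB GLMs use
  `MASS::glm.nb`; when θ diverges on equidispersed data the Poisson-limit
  fit is reported with θ at a large boundary value, flagged. The
  zero-truncated NB and ZINB likelihoods are maximised directly (BFGS;
  analytic gradients for the truncated model; standard errors from the
  numerical Hessian; truncated-NB starts from a Poisson fit with a
  method-of-moments θ).
- **Hurdle.** The two parts have orthogonal likelihoods and are estimated
  independently; combined AIC/BIC sum the parts with the total parameter
  count (AIC counts θ; BIC uses log n). The effort offset enters the count
  part only — effort scales measured biomass directly, and no assignment to
  the zero part is stated anywhere authoritative.
- **Vuong.** $z = \sqrt{n}\,\bar m / s_m$ on per-observation log-likelihood
  ratios, two-sided; an essentially zero variance of the ratios (model
  compared with itself, or an inflation component collapsed to the
  boundary) is reported as z = 0, p = 1, preferred = neither.
- **Screening.** Oceanographic/bathymetric covariates enter at the highest
  polynomial order (≤ quartic, raw powers, all lower orders included) whose
  top term is Wald-significant univariately. Distance covariates choose
  among linear, quadratic, log and inverse-log by smallest block-LRT p.
  With distances reaching zero, the log transform is `log(1 + d)` and the
  inverse-log is `1/(1 + log(1 + d))` — both defined at d = 0, monotone,
  and distinct in curvature. Climate indices choose the most significant
  lag among 0–3 months (each lag screened on the ladder, default up to
  quadratic, as fitted climate terms are quadratic in the krill models).
- **Stepwise.** The least-significant droppable unit is removed per step —
  the top order of a polynomial (marginality: lower orders never leave
  while a higher order remains) or a whole single-column term — requiring
  AIC to decrease. When only marginally non-significant terms remain, any
  drop *raises* AIC (a Wald p in (0.05, 0.157) contributes less than its
  2-unit parameter penalty); elimination then proceeds anyway with the step
  flagged `forced`, and the closing rule arbitrates: lowest AIC if it wins
  by more than 2 units, otherwise lowest BIC among models within 2 units.
  The BIC tie-break is precisely what discards such marginal terms, and
  with it the protocol recovers a planted quadratic + linear truth against
  three noise covariates in ~84% of runs (n = 3000). Ties in the
  least-significant choice break by AIC improvement, then term name.
- **Year interactions** are tested feature-by-feature by LRT (the feature's
  columns crossed with a categorical year factor, year main effects
  included), retained at p < 0.05 with an AIC improvement, accumulating
  sequentially. For hurdle models the candidate must sit in both parts;
  each part is tested separately.
- **VIF** is reported per column with the 10 (interaction) and 3
  (non-interaction) thresholds. In the analysis drivers VIF is evaluated on
  the linear portion of the final model variables: raw higher powers are
  collinear with their base terms by construction, and in the synthetic
  geometry the static covariates are deterministic functions of position,
  so high VIFs there are structural, not a fitting pathology.
- **Cross-validation** uses k = 10 folds and 20 runs, fold assignment
  seeded as seed + run; held-out predictions are on the response scale and
  pooled within a run before RMSE/MAE.

# Hotspots and overlap details

- **Weights.** Binary fixed-band, 3 km, self-inclusive (the $G_i^*$
  convention) — the band matches the survey bin scale; inverse-distance
  weights are available. The denominator uses the population SD.
- **FDR.** Benjamini–Hochberg per monthly raster, mask = adjusted p < 0.05
  and z > 0. On i.i.d. noise rasters the mask is empty in ≥ 95% of runs.
- **Rescaling.** Masked z-scores are min–max rescaled over masked cells
  only (a rescale over all cells would be dominated by the unmasked
  background); a single masked cell, or a constant masked set, maps to 1.
  A constant raster yields z = 0 everywhere, flagged.
- **AB ratio.** $AB = \overline{(p - \bar p)(b - \bar b)} / (\bar p\,\bar
  b)$; the local version drops the outer mean, so its cellwise mean equals
  the global value exactly (asserted to 1e-12). Temporal SDs use n − 1.
  Fields with zero mean make the ratio undefined and are reported as
  missing.
- **Prediction offset.** Grid predictions fix effort at one unit (log 1 =
  0): maps are per-unit-effort expected abundance, and decile classes are
  invariant to any common effort choice. Decile boundaries come from the
  pooled values of the full map set per species and scheme; boundary ties
  take the lower class.

# Problem sizes and reproducibility

The bundled analysis (`analysis/01_simulate.R` … `07_hotspots_overlap.R`)
and the acceptance script run a five-year study — 20 cruises, 1,000 bins,
120 kriged surfaces on a 600-cell grid — sized so the full chain, including
selection over 16 covariates per model part, completes in a few minutes
while every stage still has enough data to behave like the method at scale
(blue whales, at ~4% presence, are deliberately the data-starved species:
at much smaller sizes their selected model can collapse to the intercept,
which is the correct behaviour of a p-based protocol on 20 presences).
Monte-Carlo checks in the test suite use 50 seeds (kriging QC pass rate,
stepwise recovery) or 100 seeds (null calibrations of Vuong, the FDR mask
and Moran's I). All randomness flows from explicit integer seeds;
sub-seeds are drawn below 2³¹ and every generator output is a pure function
of (inputs, seed).

# Known limitations

- Global kriging only; no local search neighbourhoods, anisotropy or
  co-kriging. Consequently trend contamination mostly manifests as large
  fitted ranges rather than gate failures.
- The truncated-NB and ZINB optimisations are smooth-likelihood local
  maximisations from moment starts; pathological designs (quasi-separation,
  unidentified θ at very low counts) are reported via convergence and
  boundary flags rather than repaired.
- The stepwise path explores single-drop moves only (no all-subsets
  search); the screening alpha, drop rule and closing rule are exactly the
  stated protocol, and inherit its multiplicity behaviour (a noise
  covariate survives the four-candidate ladder ~18% of the time at
  α = 0.05).
- Persistence and AB maps are only as good as the prediction rasters; no
  uncertainty is propagated from the kriging variance or model standard
  errors into the maps.
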