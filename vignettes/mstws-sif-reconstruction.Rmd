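---
title: "Reconstructing daily SIF with moving spatio-temporal window sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing daily SIF with moving spatio-temporal window sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sifrecon)
```

## The problem

Solar-induced chlorophyll fluorescence (SIF) — the faint radiance
(W m⁻² μm⁻¹ sr⁻¹) that chlorophyll re-emits during photosynthesis — is the
most direct satellite proxy for vegetation productivity. The satellites that
retrieve it at useful spatial resolution, however, sound the ground in narrow
swaths with long revisit cycles, so on any given day most of the globe is
unobserved. `sifrecon` reconstructs a daily, gridded, gap-free SIF field at
0.05° by learning the mapping from 7-band surface reflectance (which *is*
available daily and globally) to SIF, then applying that mapping wherever
reflectance exists.

The catch, and the reason a single regression will not do, is that the
reflectance→SIF relationship is not stationary: it drifts with phenology
through the year and differs between vegetation types and regions. The
package therefore trains a *fleet* of models, one per (day of year,
sub-biome stratum), each on soundings pooled from a 16-day window around its
target day across all available years — moving spatio-temporal window
sampling (MSTWS). The window buys sample size and diversity; the
stratification preserves specificity.

## The procedure

**Footprint screening.** Soundings carry two retrieval bands and a quality
flag. Processing is three steps:

1. quality filtering (`qc_filter()`, keep flag 0 by default);
2. cross-band combination (`combine_bands()`),
   $SIF_{daily} = 0.5\,(SIF_{757} + 1.5\,SIF_{771})$, which suppresses
   independent band noise to $0.8125\,\sigma^2$ and is exactly unbiased when
   the 771 nm band carries 2/3 of the signal;
3. five-nearest-neighbour smoothing (`knn_smooth()`),
   $SIF_{smoothed} = \tfrac15 \sum_{i=1}^{5} SIF_{daily,i}$ over the five
   nearest same-date neighbours (great-circle distance, the target itself
   excluded, ties broken by sounding id), which divides independent noise by
   a further factor of 5.

Features are the mean of all reflectance cells whose centres fall inside the
footprint (`match_reflectance()`); `build_training_table()` labels each row
with its day of year and stratum.

**Stratification.** IGBP land-cover classes map to seven biome groups;
needleleaf forest, deciduous broadleaf forest, shrubland, savanna and
grassland split by hemisphere (cell-centre latitude ≥ 0 is "northern" — a
closed side had to be chosen), evergreen broadleaf forest by tropical region
(Amazon, Congo, Southeast Asia) and cropland by six continents, giving 19
model domains (`assign_model_ids()`). Water, urban, snow/ice and barren
cells are excluded from everything. Two mappings were genuinely open: mixed
forest is folded into the deciduous broadleaf group (its closest structural
analogue — there is no mixed-forest domain) and wetlands are left unmapped;
both are overridable arguments. Region outlines ship as editable bounding
boxes (`default_region_polygons()`) because any fixed polygon set is a
judgement call; a region-code raster can replace them entirely.

**Sampling rules.** For each key: pool the window samples across years
(`collect_window_samples()`); above 5 000 samples keep a seeded uniform
subset of exactly 5 000, at or below 1 000 skip the key
(`apply_sampling_rules()` — the stricter of the two floors the method
description states, applied consistently); split 70:30 into training and
validation (`split_train_val()`). The cap is applied *before* the split, so
a capped key trains on ≤ 3 500 rows; the alternative order is a config
switch. Windows wrap across the year boundary on a 365-day circle (February
29 folds onto day 60), so New-Year models pool winter samples like any
others.

**Model fleet.** Three regressor families stand behind one fit/predict
surface: gradient-boosted trees (xgboost), random forests (ranger) and a
single-hidden-layer feed-forward network (nnet). `train_model_cv()` runs
5-fold cross-validation over a small hyperparameter grid, scores by mean
held-out R², and refits the winner; `select_algorithm()` compares families
on representative keys by the same score, ties resolving to the declared
order. Selection is global by default (one family for the whole fleet, the
reading most consistent with an automated-selection workflow) with a per-key
override through `registry_config()`. Training rows are canonically ordered
by id before fold assignment so results are invariant to input row order.

**Fallbacks.** `resolve_model()` serves every query: the exact key if
trained; otherwise the same-stratum model at minimal circular day-of-year
distance (ties toward the earlier day — determinism requires picking a
side); otherwise the per-day universal model trained on that day's combined
window data; otherwise the nearest-day universal model. Nearest-date-first
ordering preserves spatial specificity, which is the point of the
stratification. `predict_grid()` applies the resolved models per cell and
records which key served each cell in a provenance layer.

**Evaluation.** `regression_metrics()` reports R² = 1 − SS_res/SS_tot (the
coefficient of determination, not squared Pearson correlation — the two
diverge exactly when the slope departs from 1, and both quantities are
reported; a flag switches conventions), RMSE, and the OLS slope of
predictions on observations. `cross_biome_report()` stratifies validation by
the 19 domains, marking unsampled domains absent rather than zero.
`compare_strategies()` trains one pooled universal model and the MSTWS fleet
on identical data with identical hyperparameter search and scores both on a
byte-identical held-out set (hash recorded). `cross_sensor_validate()`
scales airborne 755 nm SIF by 1/1.12 (the documented magnitude offset
against the satellite 757 nm band), aggregates it to the 0.05° grid by
unweighted per-cell means, and pairs it with predictions.

## The synthetic world

Real multi-year satellite archives are neither shippable nor necessary for
testing the *method*, so the package carries a generator
(`world_config()` / `generate_world()`) that produces a toy earth with
exactly the statistical structure MSTWS assumes:

- latent truth $S = \max(0,\; a_0(s, d) + a_1(s, d)\, g)$ with
  $g = b_2 - b_1$, a near-infrared-minus-red contrast; both coefficients
  follow stratum-specific annual sinusoids, so the mapping is heterogeneous
  in space and non-stationary in time — a pooled model *cannot* represent
  it, which is the property under test;
- seven reflectance bands with stratum-phased seasonal cycles, a
  deterministic spatial texture and optional Gaussian noise, clamped to
  [0, 1];
- two-band soundings $SIF_{757} = S + e_1$,
  $SIF_{771} = \tfrac23 S + e_2$, $e_i \sim N(0, \sigma_{band}^2)$ —
  the 2/3 factor makes the cross-band combination an exact inverse, so its
  noise behaviour can be isolated; a configured fraction gets failing
  quality flags;
- striped swath coverage that tiles the grid within one revisit period,
  plus dense random snapshot patches (the instrument's target/snapshot mode)
  so each region is also sampled at scattered days of year — without them a
  rigid cycle samples every location at the same one or two days per window
  and per-day models are forced to extrapolate;
- airborne-style samples at 1.12 × truth plus small noise for cross-sensor
  validation.

All 19 domains are laid out as blocks on the grid: five latitudinal bands
per hemisphere, three evergreen-broadleaf region columns, six cropland
continent columns, separated by one-cell water strips. The strips matter:
real sub-biomes are enormous relative to the 0.1° smoothing radius, but a
toy grid's are not, and without separation the five-neighbour smoothing
mixes footprints across domain boundaries (worst at the equator, where
seasonal phases oppose) and corrupts the labels with variance no model can
explain. The strips restore the scale separation the method implicitly
assumes.

Everything is a pure function of (config, seed): per-date noise streams are
derived deterministically from the world seed and the date, so any slice can
be regenerated independently.

### What the generator does not emulate

No radiative transfer, atmosphere, clouds, orbital mechanics, retrieval
physics or land-cover error; reflectance and SIF are low-dimensional
sinusoids rather than real spectra; the latent mapping is exactly linear in
one band contrast. Tests passing on this world therefore demonstrate that
the *pipeline machinery* — screening, smoothing, stratification, windowing,
fleet training, fallbacks, evaluation — is correct and that stratified
windowed sampling beats pooling *when the assumed heterogeneity is present*.
They do not certify accuracy on real archives.

## Numerical choices and problem sizes

- Default world: 40 × 80 cells of 0.05° straddling the equator, two years.
  Noise defaults — band noise 0.1 (a realistic single-sounding retrieval
  uncertainty relative to SIF values of 0–2.5), reflectance noise 0.01, 10%
  quality-flag failures — are held fixed across experiments.
- The parameter-recovery study runs noise-free (band and reflectance noise
  0, no flag failures), with gentle spatial texture (amplitude 0.01), dense
  soundings (8 per swath cell, 3 snapshot patches/day), 12 evaluated days of
  year spread over the annual cycle, and tight radii (smoothing 0.03°,
  feature matching 0.04°) so neighbourhoods stay inside one toy-scale
  stratum. Its sample floor is 300 — the toy strata cannot supply 1 000
  same-window soundings; the production floor of 1 000 is exercised at its
  default everywhere else.
- The strategy comparison uses 20 seeded replicates of a 20 × 40 world with
  default noise, two target days (60 and 244), floor 50 and cap 3 000.
- Cross-validation uses 5 folds throughout; test-suite grids are single
  configurations (the grid search itself is exercised separately) with
  150–300 boosting rounds, depth 5–6, learning rate 0.3.
- Zero-variance targets and degenerate folds are refused or skipped
  explicitly; tie-breaks (grid order, candidate order, earlier day of year,
  sounding id) are all deterministic by construction.

## Limitations

One family is selected for the whole fleet by default; per-key selection is
available but slower. The fallback chain guarantees coverage, not accuracy —
the provenance layer exists so downstream users can mask cells served by
distant substitutes. ASCII-grid rasters are single-band and carry no CRS
metadata beyond the documented EPSG:4326 convention. The universal baseline
in `compare_strategies()` shares the fleet's feature set; a baseline with
extra temporal features would be a different (and interesting) comparison.
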