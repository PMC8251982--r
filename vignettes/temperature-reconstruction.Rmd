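---
title: "Reconstructing daily air temperature from satellite LST: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing daily air temperature from satellite LST: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tagrid` reconstructs daily minimum, mean, and maximum near-surface air
temperature (Ta) on a 1 km grid by calibrating ground-station records
against satellite land-surface temperature (LST). This vignette is the
package's account of the science: the model and its assumptions, the
station quality cascade, the numerical conventions, what the synthetic
generator does and does not emulate, and the design choices made where
the design was genuinely open.

## 1. The calibration model

LST and Ta are physically related but not interchangeable: LST is the
radiometric temperature of the surface skin, and its relationship with
2 m air temperature drifts daily with cloudiness, soil moisture, wind,
and land cover. The central modelling assumption is therefore that the
LST slope is *day-specific*. For each calendar year and each outcome
(`tmin`, `tmean`, `tmax`) we fit, by REML with `lme4`:

* **fixed effects**: day and night LST, indicators for whether each LST
  value was gap-filled, monthly NDVI, an annual harmonic
  (`sin`/`cos` of `2π · time`, with `time = (doy − 1)/(days in year − 1)`),
  elevation, daily mean wind speed, a three-level season factor
  (cold-dry Nov–Feb, warm-dry Mar–Apr, rainy May–Oct), and
  season × LST interactions;
* **random effects, grouped by day**: an intercept plus slopes on day
  and night LST.

Fitting one model per year keeps the calibration local in time and makes
the cross-validation unit clean. All continuous covariates are centred
and scaled on the training rows; the stored constants are re-applied at
prediction time, so predictions are invariant to, e.g., shifting every
elevation by a constant. The outcome stays in °C. Prediction at a
cell-day adds the day's random intercept and slopes to the fixed part;
days never seen in training get the fixed part only and are flagged.

**Random-effect covariance.** The 3 × 3 unstructured covariance is
attempted first; on non-convergence the fit falls back to independent
(diagonal) effects, then to an intercept-only structure, and the level
used is recorded in the fit object (`$re_structure`). This guarantees an
answer while preferring the richer structure. Aliased fixed columns
(e.g. season contrasts in a single-season training window) are dropped
and reported. Convergence is the optimizer default (relative tolerance
~1e-6, generous iteration cap).

## 2. Station quality assessment

Heterogeneous networks — automatic, synoptic, academic, and crowdsourced
personal stations — carry different error modes, so records pass a
four-check cascade; each check sees only the survivors of the previous
one:

(a) **Short station-years** — a station with fewer than 20 station-days
    in a year is dropped for that year.
(b) **Physical limits** — station-days with a maximum below the minimum,
    negative wind, any temperature below −30 °C or above 53 °C, or mean
    wind above 114 m/s (all strict inequalities) are dropped.
(c) **Stuck runs** — repeated equal values (after rounding to 0.01 °C)
    indicate a frozen sensor; runs longer than 2 are flagged for the
    daily mean and longer than 3 for the minimum and maximum, counted
    over observed days only. Only the offending variable is removed.
(d) **Buddy check** — each observation is compared with an
    inverse-distance-weighted (power 2) interpolation from stations
    within 30 km and 500 m of elevation on the same day; squared
    differences ("deviations") above the 99th percentile of the
    non-crowdsourced deviations flag the station-day, and a station with
    ≥ 20% of its evaluable temperature-days flagged is dropped entirely.

Design decisions where the method family leaves room:

* The deviation percentile is computed **per outcome per year**,
  matching the per-year modelling unit.
* At least **3 qualifying neighbours** are required; with fewer, the
  99th-percentile null is too unstable, so the station-day is skipped
  and counted in the audit.
* A buddy-flagged day removes the **whole station-day** (all three
  outcomes), since a spatial inconsistency rarely isolates to one
  summary statistic; check (c), by contrast, is per-variable.
* The station-drop denominator is the station's days with at least one
  computable deviation in the year.
* A neighbour at zero distance receives a dominating (not infinite)
  weight, so co-located stations act as exact matches.
* Duplicate-station screening (≤ 100 m apart, ≥ 50% identical
  0.01-rounded daily means over ≥ 10 shared days) is report-only.

By construction the buddy check flags about 1% of non-crowdsourced
deviations even on clean data; the test suite asserts this rate lands in
[0.5%, 2%]. Checks (a)–(c) are pure functions of a single station's
series and are idempotent.

## 3. LST fusion, gap-filling, and wind

Two satellites' day and night LST grids are merged cell-day-wise: both
present → average; one present → that value; neither → missing, with
provenance recorded. Missing cell-days are then filled by within-year
linear interpolation between the nearest observed days `t₀ < t < t₁`:

```
y = (y₀ · (t₁ − t) + y₁ · (t − t₀)) / (t₁ − t₀)
```

Leading gaps take the next observed value unaltered and trailing gaps
the previous one; interpolation never crosses year boundaries; filled
days carry indicator flags that enter the calibration as fixed effects
(gap-filled LST is systematically less informative, and the indicators
let the model discount it). A cell with no observations at all in a year
stays missing and is excluded from prediction. The implementation is a
direct vectorisation of the formula; the test suite checks it against
`stats::approx(rule = 2)` as an independent oracle on 1,000 random
masks.

Missing station wind is imputed from the nearest station (great-circle
distance, ties broken by station id) with a value on the same day,
stepping back one day at a time when no station reported; the back
search is capped at 30 days to bound runtime. No elevation or network
restriction is imposed on wind donors. For held-out stations in
cross-validation, wind is *always* donor-imputed from training stations,
as if the test stations never reported wind — so no held-out information
reaches the model.

## 4. Grid geometry

The master grid is a regular lattice in the sinusoidal projection on a
sphere of radius 6,371,007.181 m with 926.625433 m cells — the standard
1 km LST product geometry. A study region is built from a prediction
area's bounding box by buffering 50 km outward and snapping each limit
**down** to the tenth-degree graticule. Snapping down (rather than to
the nearest tenth) is the convention adopted here: it is the one that
reproduces the conventional printed limits of study regions defined this
way, and it can only move the southern/western limits outward. Cells
whose centroid falls inside the box are retained; a station on a shared
cell edge is assigned to the lower cell index. Elevation is aggregated
from a fine DEM by a Gaussian filter (150 m SD) and centroid extraction;
monthly NDVI is the two-satellite average with single-source fallback.

## 5. Evaluation

Prediction-area stations are split into 10 folds (station-level, so a
station is never split across folds; stations outside the prediction
area always train). The metric suite per year/outcome:

* RMSE, SD of the observations, and improvement = SD − RMSE;
* R² = 1 − mean((y − p)²)/Var(y), with the sample (n − 1) variance —
  so a constant mean predictor scores slightly above 0 (by 1/n) rather
  than exactly 0;
* spatially weighted SD and RMSE, where each (day, quarter-degree lon ×
  quarter-degree lat) group shares total weight 1 (bins anchored at
  integer degrees), equalising dense and sparse subregions;
* R²_spatial (squared correlation of per-station annual means, sample
  size = stations) and R²_temporal (squared correlation of the demeaned
  observations and predictions).

The crowdsourced-network ablation runs two cross-validations that test
only on non-crowdsourced stations — one excluding the crowdsourced
network from training, one including it — and reports the difference of
the spatially weighted RMSEs (the "spatial RMSE" reading adopted here;
the unweighted difference is also returned). The learning curve fixes
the two folds whose per-fold RMSE is closest to the overall CV RMSE as a
standing test set, then trains on growing random subsets (by default
10·r stations and 2,500·r observations in round r, 100 replicates).
Wind donors for its test predictions are the selected training
stations' full series: imputation is preprocessing, while the sampling
applies to outcome observations.

## 6. What the synthetic generator emulates

The generator provides the study conditions for every test:

* a sinusoidal-lattice region with a smooth elevation field spanning
  1,400–4,500 m — warm lowland valleys through cold highlands, giving
  annual mean temperatures of roughly 4–26 °C under the default lapse
  rate of −6.5 °C/km — and monthly NDVI with a rainy-season peak;
* daily Ta fields = linear predictor (lapse, annual harmonic, NDVI) +
  day random intercept (SD 2 °C, the synoptic component) + spatially
  correlated residual (SD 0.8 °C); minimum/maximum offset from the mean
  by strictly positive lognormal half-ranges, so ordering holds by
  construction;
* LST = a_j + b_j · Ta + noise per satellite, with day-specific slopes
  b_j ~ N(0.6, 0.15) and 2 °C noise, day LST driven by the maximum and
  night LST by the minimum; cloud missingness as spatially correlated
  blobs hitting a target fraction per day;
* multi-network stations (reference and crowdsourced) with 0.5 °C
  observation noise, and planted, exactly labelled violations (short
  records, impossible/implausible values, stuck runs, gross single-day
  spikes) injected after truth sampling.

Spatial correlation is Gaussian-filtered white noise throughout — the
cheapest field with a controllable range. All generators are
deterministic under a seed, and one pipeline seed fans out to per-stage
seeds.

Two generative directions are deliberately kept separate. The *physical*
direction above (Ta drives LST) feeds the end-to-end and pipeline tests.
For parameter recovery, `simulate_from_model()` generates the outcome
from the calibration design itself (known standardized coefficients +
day random effects + residual), so the model is exactly correctly
specified and held-out RMSE should approach the generative residual SD —
which the tests assert (CV RMSE within [0.9, 1.3] of a 1.0 °C residual
scale, coefficient recovery to 1e-3 in the noise-free limit, 3-SE
coverage across seeded replicates).

What the generator does **not** emulate — and hence what passing tests
do not show about real data: orographically organised weather (residual
correlation is isotropic), urban heat islands and land-cover-dependent
LST bias, retrieval artefacts correlated with the cloud mask, instrument
drift and siting biases beyond the planted artifact types, humidity, and
non-Gaussian error tails. Results on synthetic data demonstrate the
pipeline's correctness and internal calibration, not its field accuracy.

## 7. Numerical conventions and degenerate inputs

* Quantiles (buddy threshold, percentile surfaces) use the
  linear-interpolation definition (R type 7).
* Leap years use a 366-day denominator in the time covariate.
* NDVI is matched by the observation's calendar month.
* Temperatures are °C internally; differences are reported as K
  (numerically identical).
* "Noise-free" recovery simulations use a residual SD of 1e-6 °C rather
  than exactly zero so the REML fit stays well-posed.
* Single-season training windows drop the season terms (they are
  aliased with the intercept); the dropped columns are recorded.
* Empty folds, rounds larger than the station pool, and stations
  without wind donors fail or skip with explicit, named messages.
* Person-day thresholds are inclusive (Tmin ≤ 5 °C, Tmax ≥ 30 °C),
  matching how extreme-day maps are conventionally drawn; both
  thresholds are arguments.
* Population polygons are allocated to cells by areal weighting
  (Sutherland–Hodgman clipping against cell rectangles); totals are
  conserved to floating-point accuracy. No dasymetric refinement is
  attempted.

## 8. Problem sizes used by the test suite

The suite exercises the full protocol at desk scale, chosen to keep a
complete run in a few minutes: a 15 × 15 cell region with 25 stations
for unit tests; 20 × 20 cells with 50 stations and one full year for the
quality-cascade fidelity, parameter-recovery (20 replicates), and
cross-validation checks; learning-curve rounds of 4–16 stations and
800–3,200 observations with 20 replicates. The full-scale protocol
(10·r stations, 2,500·r observations, 7 rounds, 100 replicates) remains
the function default.

## 9. Known limitations

* The mixed model is linear in LST within a day; strongly nonlinear
  surface–air decoupling (e.g. snow cover, strong inversions) is only
  absorbed by the day random effects.
* Gap-filling is purely temporal; a cell missing for a long stretch is
  filled by a straight line regardless of its neighbours' weather.
* The buddy check assumes enough near, elevation-similar neighbours;
  isolated stations are never screened spatially (they are skipped and
  audited instead).
* Station-level CV measures interpolation skill within the monitored
  envelope; accuracy in cell types never sampled by any station (e.g.
  high summits) is unidentified.
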