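---
title: "Methods: neighbourhood-scale PM mapping from a low-cost monitor network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neighbourhood-scale PM mapping from a low-cost monitor network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmscape)
```

# The problem and the pipeline

A handful of low-cost optical particulate-matter (PM) monitors, scattered over
a town by a citizen network, measure PM1, PM2.5 and PM10 at their own
locations only. `pmscape` turns such a network into daily and period-average
concentration maps in five stages:

1. **Calibration.** Raw optical readings are biased by design (humidity
   growth of hygroscopic particles, offset and gain drift). A ridge-penalized
   polynomial regression of reference concentrations on (raw PM, temperature,
   relative humidity) — all monomials and pairwise interactions to total
   degree 2 by default — inverts the distortion.
2. **Feature engineering.** Each (location, day) becomes a vector of 151
   named features drawn from the monitor network, daily reanalysis-style
   meteorology at nine grid points, and rasterized road vectors.
3. **Model.** One small multilayer perceptron per PM size: hidden layers of
   100, 100 and 10 rectifier units with dropout 0.2/0.2/0, a linear output,
   mean-absolute-error loss, Adam, batches of 24, 20 epochs.
4. **Evaluation.** Entire monitors are held out (never time slices), so the
   model is scored at locations it has never seen; RMSE, symmetric MAPE,
   R², Pearson's r, a weekly-profile shape check, and a one-at-a-time (OAT)
   sensitivity ranking.
5. **Mapping.** The per-size networks are applied to every cell centre of a
   10 × 20 grid of 600 m cells (200 points) for every day, then averaged.

A synthetic-town generator supplies all inputs with known ground truth, so
every stage is testable without external data.

# The feature vector

The default configuration is a fixed contract of 151 features, in a stable
documented order:

| block | features | count |
|---|---|---|
| calendar | day-of-week (Mon = 0), month index | 2 |
| seasonality | day-of-year sine, cosine | 2 |
| position | easting, northing (m, local frame) | 2 |
| wind | centre wind speed, wind-from direction | 2 |
| meteorology | 12 variables × 9 points (C + 8 cardinal/ordinal) | 108 |
| network average | per-size mean PM over available monitors | 3 |
| nearest 3 monitors | PM1/PM2.5/PM10, distance, bearing, upwind flag | 18 |
| interpolation | per-size IDW (power 2) of the 3 nearest monitors | 3 |
| difference | per-size (average − IDW) | 3 |
| roads | vertex-count density per road category | 8 |

The 12 meteorological variables are boundary-layer height and dissipation,
total precipitation, mean precipitation rate, 10 m wind components,
2 m temperature and dewpoint, surface pressure, cloud cover, wind gust and
net solar radiation. Every block can be switched off in `feature_config()`;
the default asserts length 151.

Conventions that the tests pin down:

* **Upwind flag.** A monitor is upwind (1) when the angular difference
  between the bearing from the point to the monitor and the meteorological
  wind-from direction is ≤ 90°; calm wind gives 0. Reversing the wind flips
  the flag except exactly at the boundary.
* **IDW.** Weights are `1/max(d, 1 m)^2`; a distance under 1 m is an exact
  hit and returns that monitor's value.
* **Road density.** Polyline vertices are binned into a 4 m raster per
  category (a 50 m raster is available in configuration, reflecting the
  coarser convention sometimes used for road-density indices); the density at
  a point is the sum over cells intersecting a square window of side 200 m —
  read as a 200 m-side square, since a literal 200 m² square (14 m side)
  would rarely contain a road.
* **Leakage.** Feature engineering runs separately for training and
  evaluation stations. A training row never sees its own station in its
  neighbour set *or* in the network average (the average would otherwise leak
  the target). Evaluation rows see training monitors only, so the evaluation
  table is bit-invariant to any perturbation of evaluation-station
  concentrations — a property asserted in the tests.
* **Missing data.** Hourly series are averaged into UTC days with a 75%
  coverage floor (configurable); missing monitor values are imputed by that
  station's training-period median, and a row is dropped only when none of
  its neighbours has any record.

# The network and its numerical choices

Features are z-scored with training-set statistics (mixed units — metres,
µg m⁻³, counts — would otherwise dominate the geometry of optimisation). The
target is standardized internally with training statistics and
back-transformed at prediction; history metrics are reported in original
units. Initialisation is He-scaled normal; batch order, initialisation and
dropout masks all derive from one seed, so a run is bit-reproducible on one
platform (floating-point reduction order may differ across BLAS builds). The
learning rate defaults to Adam's conventional 1e-3; the last incomplete batch
is kept.

Two deployment guards apply at prediction time, both standard practice for
MLP regressors applied outside their training envelope and both inert
in-envelope:

* features with zero training variance are held at their training value (the
  network never saw them vary, so any response through them would be
  untrained noise);
* each standardized feature is saturated at its fit-time minimum/maximum,
  because rectifier networks extrapolate linearly without support; before
  this guard, out-of-range static features at held-out locations could
  dominate a prediction.

The OAT sensitivity analysis perturbs each standardized feature by ±1
standard deviation (configurable), holding others fixed, and scores the mean
absolute prediction response over rows and both signs. It bypasses the
saturation guard, since its object of study is the network's local response.
On a linear model the score is exactly |coefficient| × σ, which the tests
assert; constant features score 0 and are flagged.

Metric conventions: SMAPE uses the half-sum denominator,
`100/n · Σ |ŷ−y| / ((|y|+|ŷ|)/2)`, bounded by 200%, with 0/0 terms defined
as 0 — SMAPE values are only comparable within one variant, so this choice is
stated prominently. R² is `1 − SS_res/SS_tot` against observations, not a
squared correlation. Degenerate cases (constant observations) return NA with
a flag rather than a fabricated value.

# The synthetic town

`make_town()`, `simulate_met()`, `simulate_pm()` and `distort_sensor()`
generate a complete virtual study area with known truth. The design goal is a
field with the structure a real town's PM field shows, at the scales the
monitor network can resolve:

* **Roads.** Eight categories of random polylines. Through roads (motorway,
  A, B) cross the domain; local categories cluster around three district
  centres, because real road networks are organised into districts and
  corridors rather than scattered uniformly.
* **Background.** A positive AR(1) day series (mean 8 µg m⁻³) multiplied by
  a smooth spatial surface, `1 + 0.3·exp(−d²/2s²)` with `s = 2.5 km` around
  the town centre — the spread, kilometre-scale urban-background elevation
  (secondary aerosol and the general urban increment) that monitor networks
  can interpolate.
* **Road sources.** Per-category coefficients times the local road density,
  diluted by boundary-layer height (`500 m / BLH(t)`) and washed out by
  precipitation (`exp(−50 · precip)` per metre of daily total), giving
  roadside increments of a few µg m⁻³ — the magnitude observed next to busy
  urban roads.
* **Day noise.** A day-level lognormal factor (σ = 0.1) shared across space,
  so the truth field stays exactly evaluable at any point and monitor series
  equal the field at their locations — a conservation property the tests
  assert. Sensor-level noise lives in `distort_sensor()` instead:
  `raw = a0 + a1·pm + a2·pm² + b1·RH·pm + N(0, σ)`, with parameters stored so
  calibration recovery is checkable.
* **Monitors.** Eight stations at ≥ 500 m separation placed as a citizen
  network: most at residential locations across the districts, two along
  busy roads. Station ids mirror the study design of holding out the
  *typical* stations: ids 2, 7 and 8 go to the monitors whose expected local
  source strength is closest to the network mean and that sit nearest the
  network centroid; the leave-monitors-out split then evaluates at
  representative, surrounded sites.
* **Sizes.** Cumulative mass shares 0.90 / 0.97 / 1.00 for PM1 / PM2.5 /
  PM10, so the coarse fraction is ≤ 10% of total mass.
* **Calibration data.** `simulate_colocation()` emulates a colocation
  campaign spanning roughly 2–40 µg m⁻³ with wide temperature and humidity
  ranges; calibrating on one field monitor's narrow range instead biases
  cleaner stations upward through quadratic extrapolation, which motivated
  the colocation design.

What the generator does **not** emulate: explicit plume transport (advection
appears only through spatially coherent met perturbations), chemistry,
station-specific noise correlated in time, seasonal source changes, or the
file layout of operational reanalysis archives beyond the reader contract.
Passing tests on this generator therefore demonstrate the pipeline's
mechanics and its statistical behaviour under a plausible field, not
performance on any real network.

# What the leave-monitors-out design can and cannot learn

With five training stations, every *static* feature (position, road
densities, neighbour geometry) takes exactly five distinct values, so static
features span a rank-5 space. The attribution of between-station differences
to roads versus position versus neighbour distance is therefore
under-determined: models that fit the training stations equally well can
disagree arbitrarily at unseen locations. We verified this during development
with oracle regressions — a ridge restricted to the 8 road features transfers
to the full map far better than the same ridge given all static features, as
any honest model must be. The held-out RMSE surface is more forgiving because
the held-out stations are the typical, well-interpolated ones: the packaged
study meets "held-out RMSE below the between-monitor spatial spread" at the
canonical seed, while the period-average map correlation with the truth field
(reported by the acceptance script and asserted in the acceptance suite)
falls short of the 0.7 mark. This identifiability ceiling is a property of *any* model under this
design, not of the network; the practical remedy is more stations or an
informative prior tying concentrations to roads, both outside this package's
scope.

# Problem sizes used by the tests

The test suite and the acceptance script run entirely on generated data,
sized so the whole suite completes in a few minutes on one CPU: the full
study uses 180 days × 8 monitors with a 200-cell map; unit tests use a
cached 40-day town; the linear-recovery check trains on 4 800 rows (60 dates
× 80 points, 200 Adam steps per epoch); calibration recovery uses 20 seeds of
180 colocation pairs; the OAT noise-feature check trains 20 networks on the
180-day study table. The noiseless linear-recovery check runs with dropout
off: dropout is a noise regularizer, and the check's purpose is optimisation
fidelity on a clean signal.

# Known limitations

* Map-scale spatial attribution is weakly identified from five stations (see
  above); period-average maps should be read as interpolations informed by
  roads, not as validated roadside exposure estimates.
* SMAPE comparisons across publications require matching the variant.
* Geographic readers accept WGS84 (EPSG:4326); national-grid sources must be
  converted upstream. netCDF meteorology requires the optional `ncdf4`
  package; the long-CSV form is always available.
* The rasterization resolution default (4 m) and the 200 m window are the
  feature-engineering convention; a 50 m raster is available where the
  coarser road-density convention is wanted.
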