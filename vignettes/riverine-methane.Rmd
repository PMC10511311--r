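---
title: "Estimating riverine CH4 emissions: models, corrections and uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating riverine CH4 emissions: models, corrections and uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riverch4)
```

## The estimation problem

Rivers and streams emit methane by two pathways: diffusion across the
water-air interface, and ebullition (bubble release from sediments).
A bottom-up emission estimate for a river network multiplies, for every
reach and month, a diffusive flux rate by the water surface area that is
actually exchanging gas. The flux rate follows Fick's law,

$$F = k_{CH_4}\,(C_w - C_{eq}),$$

with $k_{CH_4}$ the gas-transfer velocity (m d$^{-1}$), $C_w$ the
dissolved CH$_4$ concentration and $C_{eq}$ the concentration in
equilibrium with the atmosphere (both mmol m$^{-3}$). Every one of these
terms must itself be modelled from what is observable at network scale:
discharge, channel slope, climate, and a sparse archive of point
measurements. This package implements that chain end to end, with the
corrections and uncertainty propagation the estimate needs to be
physically credible, and ships a synthetic-data generator so the whole
chain can be verified against planted ground truth.

## Hydraulics and effective area

Reach hydraulics come from downstream hydraulic geometry: power laws
$V = a_V Q^{b_V}$, $W = a_W Q^{b_W}$, $D = a_D Q^{b_D}$ applied to each
reach's monthly mean discharge. The coefficients are configuration
(`hydraulic_coefficients()`), with literature defaults
($a_V{=}0.19, b_V{=}0.29$; $a_W{=}7.2, b_W{=}0.5$; $a_D{=}0.27,
b_D{=}0.39$); any upscaling run should pin and report the set it uses.
Surface area is $W \times$ reach length; *effective* area further
multiplies by the ice-free fraction and one minus the dry fraction of
each month, because ice-covered and dry channels are taken not to emit.
The multiplicative form is the simplest contract consistent with
treating the two as independent period fractions.

Resolved hydrography misses the smallest channels.
`extrapolate_small_streams()` extends each basin group downward with
Horton-style geometric ratios (width ratio, total-length ratio per order
step), terminating before widths fall below 0.3 m — the median width of
the smallest field-surveyed streams. The synthetic orders inherit the
k600, CH$_4$ concentration and — a choice this package makes explicit —
the ice/dry fractions of the basin's first-order reaches.

## Gas exchange

The transfer velocity standardized to Schmidt number 600 follows the
slope-velocity scaling

$$k_{600} = S \times V \times 2841 + 2.02 \quad [\mathrm{m\,d^{-1}}],$$

with coefficient standard deviations 107 and 0.209 carried into the
Monte Carlo stage. Conversion to CH$_4$ uses
$k_{CH_4} = k_{600}\,(Sc_{CH_4}/600)^{-1/2}$ with the freshwater CH$_4$
Schmidt polynomial (cubic in temperature, 600 near 17.4 °C).
$C_{eq}$ combines a natural-log solubility function at zero salinity, an
atmospheric mixing ratio of 1.83 ppm (2010-2020 mean), and barometric
pressure $e^{-z/H}$ with scale height $H = 8500$ m. Water temperature is
a linear map of air temperature floored at 0 °C; the floor (rather than
dropping sub-zero months) keeps frozen-but-flowing months in the totals,
where the ice-free fraction already discounts them.

Negative fluxes (influx into undersaturated water) are retained and
summed signed; clipping them would bias totals upward.

## The supply-limitation correction

Applying a reach-average $k$ to a locally measured concentration can
produce fluxes that exceed the CH$_4$ stock the reach can supply —
conspicuously in steep mountain reaches. The gas footprint length

$$F_L = \frac{3V}{K}, \qquad K = k/D \ \ [\mathrm{d^{-1}}]$$

is the upstream distance over which ~95 % of the dissolved gas evades.
$V$ is converted to m d$^{-1}$ before use, since $K$ is a per-day rate;
the conversion is verified by the algebraic identity below. When $F_L$ is *shorter* than the reach length $R_L$,
the modelled concentration cannot be maintained along the whole reach:
the computed evasion would exceed the advective supply. The correction
reduces $k$ so that $F_L = R_L$ exactly:

$$k \leftarrow \min\!\left(k,\ \frac{3 V D}{R_L}\right).$$

Written as a clamp, the correction (i) only ever decreases $k$, (ii) is
idempotent, (iii) makes the recomputed footprint equal $R_L$ on every
corrected reach, and (iv) enforces the mass balance that per-reach
evasion never exceeds $3\times$ advective throughput. Note the
correction direction: it engages when $F_L < R_L$. The alternative
reading (correcting when $F_L \ge R_L$) would *increase* $k$ and violate
both the mass balance and the requirement that corrected totals not
exceed uncorrected ones, so it cannot be the intended rule.

Corrections here operate on the CH$_4$-specific $k$ actually used in
Fick's law, not on $k_{600}$ before Schmidt conversion. Correcting
$k_{600}$ instead would re-inflate $k_{CH_4}$ above the $3VD/R_L$
ceiling whenever the Schmidt number is below 600 (water warmer than
about 17 °C), breaking the mass balance the correction exists to
enforce.

Two alternative corrections are implemented for comparison: capping $k$
at 35 m d$^{-1}$ (the threshold above which bubble-mediated transfer
dominates) and capping flux rates above two standard deviations of the
mean. For the latter, the population statistics are computed once on the
uncorrected rates — by default per calendar month, with a pooled-annual
switch — and negative rates are never capped (the cap addresses the
high-outlier artefact only). A single-pass cap with frozen statistics is
deliberately not idempotent under re-application; re-capping a capped
population would recompute a lower threshold and progressively shrink
genuine variability. The supply-limited option is the default reported
configuration.

## Concentration modelling

Dissolved CH$_4$ is modelled on the log scale with one random forest per
calendar month, each trained on a three-month window (the target month
and its neighbours, December-January wrapping) to stabilize months with
thin coverage, with an 80/20 train/test split under a recorded seed.
Hyperparameters are pinned configuration: mtry 13 (capped at the number
of predictors), min.node.size 8, 1200 trees. Before fitting, predictors
are pruned so no retained pair has $|r| > 0.95$ (an ordered
keep-priority list decides which member survives) and highly skewed
columns are log-transformed with an offset for zeros.

Aggregation of observations to reach-months is two-stage — across years
within site-month, then across sites within reach-month — with the
statistic at each stage switchable between mean and median. The default
is mean at both stages; both statistics are defensible here (means
compose with totals, medians damp the extreme values endemic to CH$_4$
data), so the choice is exposed as configuration rather than hidden.

Per-prediction uncertainty is the infinitesimal-jackknife standard error
of the ensemble mean, as implemented by the `ranger` backend (with a
spread-across-trees fallback when the jackknife is numerically
unavailable; the method used is recorded). The jackknife routine draws
on the session RNG, so predictions pin the RNG to the fit seed — without
this, repeated predictions from the same model differ slightly and
pipeline reruns are not reproducible. Back-transformation to
concentration units uses $\exp(\hat\mu)$ with delta-method s.d.
$\exp(\hat\mu)\,\mathrm{se}$; a lognormal bias-correction switch
($\times e^{se^2/2}$) exists and defaults to off, so point predictions
are medians rather than means of the predictive distribution. Reported
test RMSE is in the fitted (log) response units.

The extrapolation flag marks prediction rows with any predictor outside
the training 1st-99th percentile range. This is an intentional
simplification of convex-hull extrapolation-domain procedures: it is
conservative per predictor, blind to joint (correlation) structure, and
cheap at network scale.

The modelling layer is backend-agnostic: any list providing
`fit`/`predict`/`importance` closures can replace `regressor_ranger()`,
changing numbers but no interfaces.

## Monte Carlo uncertainty and sensitivity

Three uncertainty sources propagate to totals: the two $k_{600}$
coefficients (Normal around their published means), the modelled
concentration (Normal around $\hat C$ with the jackknife s.d.), and
river area via a width multiplier (Normal with s.d. equal to the
discharge CV, since width scales with discharge). Coefficient draws are
shared across reaches within an iteration — they are global model
parameters — while concentration draws are independent per reach-month
row (the resolution at which the s.d. is defined) and width multipliers
are drawn per reach and shared across its months. Draws are clamped at
zero (`pmax(0, .)`) rather than redrawn; with the s.d. magnitudes in
play the clamped mass is small, and clamping keeps the draw count and
RNG stream fixed. The active flux correction is re-applied inside every
draw. Both the 5th-95th and 10th-90th percentile pairs are reported,
since both conventions are in circulation for this quantity; neither is
privileged.

One-at-a-time sensitivity shifts each of the three parameters by
$\pm 1$ s.d. with the others at their means — six deterministic runs —
and reports totals against the baseline.

## Ebullition

Ebullitive fluxes are scarce and noisy, so they are scaled from
diffusive fluxes: observations carrying both pathways (a pair here is
one observation record, i.e. the same site and sampling occasion) are
filtered to fluxes $\ge 10^{-4}$ mmol m$^{-2}$ d$^{-1}$ on both
pathways and to k600 not modelled from hydraulic relationships, then
log ebullitive is regressed on log diffusive (natural log internally).
The upscaled central estimate applies the fitted relation to the central
diffusive total in log space — deliberately to the total rather than
reach by reach, since ebullition observations are far too sparse to
support spatially explicit scaling. The
uncertainty interval composes the regression prediction interval with
the Monte Carlo distribution of the diffusive total: lower prediction
bound at the diffusive 2.5th percentile, upper bound at the 97.5th.

## Temperature dependence

The apparent activation energy $E_M$ (eV) is the slope of
$\ln F$ on the Boltzmann-standardized temperature
$x = 1/(k_B T_c) - 1/(k_B T)$, with $T_c = 15$ °C, so $x = 0$ at the
reference temperature and the slope is $+E_M$ (verified by the
$T = T_c$ zero and by parameter recovery on planted Arrhenius data).
Fits are computed per site — by default for sites with more than 20
usable observations, a threshold that is configurable because the
plotting convention and the distributional summary need not use the
same set — and pooled over all observations. Non-positive fluxes cannot
enter a log regression and are excluded with a reported count.
`compare_em_distributions()` contrasts the riverine per-site $E_M$
distribution with a reference set (lakes, wetlands, rice paddies) via a
two-sided Wilcoxon rank-sum test, medians, IQRs and kernel densities.

## What the synthetic generator does and does not emulate

`generate_network()` builds tree-structured basins with lognormal
lateral discharge accumulating downstream, Strahler orders from the
topology, slopes declining with order, sinusoidal seasonality peaking in
the local summer, and ice-free fractions tied to a deterministic
latitude-elevation climatology. `generate_observations()` plants three
recoverable signals: a log-linear concentration model on named
predictors, a Boltzmann factor $e^{E_M x}$ on diffusive fluxes
(default $E_M = 0.17$ eV, the weak temperature dependence characteristic
of running waters), and a log-log ebullition relation (default slope 1,
around the 1:1 line). Site categories get planted concentration
multipliers so exclusion rules have measurable effects, and a small
fraction of sites is displaced 1-3 km to exercise snapping thresholds.
Observation counts per site follow lognormal weights, mimicking the mix
of one-off surveys and long time series in real archives.

The generator is deliberately not geographically realistic: no braided
or distributary channels, no spatial autocorrelation in predictors or
concentration errors, no under-ice storage, no measurement-method biases
beyond lognormal noise. Passing tests therefore demonstrate that the
pipeline recovers known structure under its own model class — not that
the model class captures every feature of real rivers.

Distributional choices in the generator (lognormal discharge and reach
lengths, beta-distributed cover fractions, sinusoidal seasonality) are
pragmatic conventions for this kind of plumbing, documented in code, and
make no claim beyond plausibility.

## Numerical conventions

* Months use non-leap calendar lengths; totals convert
  mmol $\to$ g via the molar mass 16.04 g mol$^{-1}$ (1 mmol = 16.04 mg)
  and g $\to$ Tg via $10^{-12}$.
* Latitude bands are half-open $[lo, hi)$ south to north, the
  northernmost closed at 90°, so band totals sum exactly to the global
  total.
* Zero-discharge months have zero width and area by the power laws;
  zero-spread flux populations pass through the flux cap unchanged;
  constant predictor columns are dropped with a warning.
* Site-reach distances are great-circle metres; snapping is exact
  nearest-neighbour (validated against a brute-force search in tests).
* All stochastic stages take explicit integer seeds, recorded in the
  run manifest; `run_pipeline()` reruns are bit-identical.

## Interfaces

The exported functions are the pipeline's interface; `run_pipeline()`
executes the stages in dependency order on synthetic data and returns
every intermediate product plus a manifest (seed, configuration hashes,
stage row counts), optionally writing CSV/JSON outputs. Reach tables use
12 suffixed monthly columns (`q_01..q_12`, `ice_01..ice_12`,
`dry_01..dry_12`) and are plain delimited text end to end.

## Problem sizes

The test suite exercises networks of 20-60 reaches with 150-600
observations, Monte Carlo runs of up to 1000 iterations, and
recovery studies of 100 seeds at 500 observations each; these sizes are
chosen so the planted-truth recovery checks have adequate power while
the whole suite stays fast enough to run routinely. Results quoted in
the README come from those runs and from nothing else.

## Known limitations

* Global-scale emission totals depend on real continental hydrography
  (millions of reaches) and a real predictor stack; they are not
  reproducible at package-test scale and are not claimed.
* The extrapolation flag understates multivariate extrapolation (range
  check only).
* The ebullition upscaling applies a site-level regression to a global
  total; it inherits that approximation from the stated procedure.
* Reservoir/impoundment emissions, dry-riverbed emissions, under-ice
  storage-and-release, and chemical enhancement of gas exchange are out
  of scope.

```{r example, eval = FALSE}
# A complete small run:
res <- run_pipeline(synth_config(n_reaches = 50, seed = 1), mc_n = 1000)
res$totals$global_tg
res$mc$percentiles
res$ebullition$central_tg
```
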