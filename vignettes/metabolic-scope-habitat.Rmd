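---
title: "From aerobic scope to thermal habitat: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From aerobic scope to thermal habitat: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aerohab)
```

`aerohab` couples a laboratory-derived physiological model to gridded ocean
temperature scenarios. This vignette is the package's account of the science
in that chain: the models, the numerical conventions, the synthetic-data
design, and the limits of what the package can and cannot show.

## The physiological model

Aerobic metabolic scope, MS = MMR − SMR, is the oxygen budget a fish can
allocate beyond maintenance. The package models its two components
separately:

* **SMR** (standard metabolic rate) grows exponentially with temperature,
  $SMR(T) = a e^{bT}$, with scale $a$ (mg O$_2$ kg$^{-1}$ h$^{-1}$) and rate
  $b$ (°C$^{-1}$). This is the classical thermal dependence of maintenance
  metabolism over an ectotherm's viable range.
* **MMR** (maximal metabolic rate) follows a skewed unimodal curve
  $MMR(T) = \delta x^{\omega} e^{-\omega x}$ with
  $x = (T_m - T)/(T_m - T_{act})$: it peaks at $T = T_{act}$ (where
  $MMR = \delta e^{-\omega}$), falls to zero at $T = T_m$, and rises slowly
  from the cold side. For $T > T_m$ the expression has a negative base; the
  package defines MMR ≡ 0 there, consistent with $T_m$'s meaning as the
  temperature at which maximal aerobic performance is extinguished. Scope
  beyond $T_m$ is then $-SMR(T)$, i.e. strictly non-viable.

Because SMR keeps rising while MMR collapses, MS is unimodal with an optimum
$T_{opt}$ below $T_{act}$ and a zero crossing $T_{crit}$ between $T_{opt}$
and $T_m$. Neither point has a closed form, so `curve_summary()` locates
$T_{opt}$ by dense grid search (0.001 °C resolution over $[0, T_m]$,
configurable) and $T_{crit}$ by bisection on $(T_{opt}, T_m]$ — a root is
always bracketed because $MS(T_m) = -SMR(T_m) < 0$. The resolutions are
documented precisely so that tests can pin values.

The packaged parameter sets (`species_params()`) describe a temperate
native, the salema, and a warm-adapted invader, the marbled spinefoot:

```{r}
curve_summary(species_params("salema"))
curve_summary(species_params("spinefoot"))
```

Parameters are stored at the precision at which they were fitted and
reported (one decimal for temperatures); curve summaries inherit that
uncertainty, so downstream checks should treat ~1 °C as the meaningful
resolution of $T_{opt}$ and $T_{crit}$, and the MS maxima as indicative
rather than exact.

## Respirometry processing

`process_trace()` implements the standard intermittent-flow chain with the
following fixed conventions:

* **Phase slopes.** Each closed phase is trimmed by 2 min at both ends
  (mixing transients after pump switching) before an ordinary least-squares
  line of O$_2$ concentration on time; phases with fewer than 5 trimmed
  samples are skipped with a warning. Phases whose saturation dips below
  80% are flagged hypoxic and excluded: scope is defined in normoxia.
* **Background respiration.** Blank slopes measured before and after the
  trial are interpolated linearly in time and subtracted. With no blanks
  the correction is the identity (with a warning).
* **Rates.** $\dot{M}O_2 = |slope| (V_{resp} - V_{fish})/m$. The fish's
  body volume (default mass / 1 kg l$^{-1}$) is subtracted from the chamber
  volume — the fish displaces water, so the effective respirometer volume
  is what remains.
* **MMR** is the rate of the *first* post-chase closed phase, not the
  maximum over the trial: the protocol chases fish to exhaustion
  immediately before sealing the chamber, so later phases track recovery.
  A `mode = "max"` variant exists for other protocols but is not the
  default. Note that the first-phase estimate is attenuated by recovery
  *within* the phase: with e-folding recovery time $\tau$ the OLS slope
  estimates the window-mean rate
  $SMR + (MMR - SMR)\,\bar{e}$, $\bar{e} = \tau(e^{-t_0/\tau} -
  e^{-t_1/\tau})/(t_1 - t_0)$ over the trimmed window $[t_0, t_1]$ — about
  8% low for $\tau = 1.5$ h. The tests assert against this analytic value
  rather than pretending the protocol is unbiased.
* **SMR** is the 0.15 quantile of the per-phase rates over the ~24 h trial,
  computed with linear interpolation between order statistics at rank
  position $(n-1)q$ (R's type-7 convention). The convention is stated
  because different quantile definitions differ by several mg O$_2$
  kg$^{-1}$ h$^{-1}$ at $n \approx 48$.
* Records with MMR < SMR are rejected: a measured negative scope at the
  acclimation temperature indicates a failed trial, not biology.

## Curve fitting

SMR and MMR are fitted separately (each model against its own records) by
Levenberg–Marquardt nonlinear least squares (`minpack.lm::nlsLM`, relative
tolerances 10$^{-15}$), then merged with `combine_fits()`. Starting values:
for SMR, the exact solution of the log-linear regression; for MMR,
$T_{act}$ at the warmest-performing observation, $T_m$ 5 °C beyond the
warmest observation, $\omega = 1$, $\delta = \max(MMR)\,e$. Positivity of
$\delta$ and $\omega$ is enforced by box bounds; the ordering
$T_m > T_{act}$ is not a box constraint, so it is verified at the solution
and violations (or active bounds) set a `boundary` flag instead of being
silently accepted — in practice the flag only trips on degenerate designs.

Fitting is per fish rather than per temperature-group mean: group means
would discard the information about inter-individual spread that the
standard errors rest on.

Two identifiability facts worth knowing:

* $T_m$ is only well determined when the declining limb of MMR is observed.
  A design truncated below the MMR peak (as happens for a warm-adapted
  species measured over a temperate ladder) leaves $T_m$ an extrapolation
  with standard errors of several °C.
* The salema's upper acclimation groups cannot exist in nature — fish die
  beyond $T_{crit}$ — so a real salema dataset has only four temperatures
  and `fit_mmr()` (which requires five distinct temperatures) cannot run on
  it alone. Recovery studies therefore use the synthetic generator with the
  mortality rule disabled, which *does* produce the counterfactual warm
  groups: their MMR and SMR values are perfectly good draws from the two
  curves even though their difference is non-viable, and the two curves are
  fitted separately.

`validate_predictions()` closes the loop: observed scope is regressed on
predicted scope through the origin ($slope = \sum xy / \sum x^2$, uncentred
$r^2$, t test of the slope against 1). Forcing the origin is deliberate — a
model predicting zero scope should be credited only if observations agree.

## Habitat projection

* **THS.** $THS_i = \sum_t \max(0, MS(T_{i,t}))/(N\,MS_{max})$. Negative
  scope is clamped to zero *before* averaging: temperatures beyond
  $T_{crit}$ are equally non-viable whether they miss by one degree or ten,
  and without clamping THS could leave [0, 1]. $MS_{max}$ is the species'
  *curve* maximum (from `curve_summary()`), not the field-wide maximum of
  realised scope — this keeps THS comparable across scenarios, regions and
  resolutions.
* **Depth averaging.** Fields with a depth axis are reduced by a
  thickness-weighted mean over the layers above 30 m (configurable), the
  depth range both species occupy; layers straddling the cutoff contribute
  only their upper part, and shallower water columns average what they
  have.
* **Threshold.** `derive_threshold()` finds the THS isoline enclosing 95%
  of occurrences, i.e. the 5th percentile (type 7) of THS sampled at
  occurrence cells; occurrences on land cells are excluded with a warning.
  The packaged demo threshold is 0.62. **QMS** is 1 strictly above the
  threshold — ties count as unsuitable, a fixed tie-break so maps are
  bit-stable. QMS thresholds the *decadal* THS, not the daily NMS; an
  alternative daily-exceedance reading exists but is not implemented.
* **CF** = QMS(native) − QMS(invader) ∈ {−1, 0, +1}, antisymmetric under
  species swap. `summarize_coexistence()` reports area-weighted percentages
  of the three classes; cell areas default to the spherical formula
  $R^2\,\Delta\lambda\,\Delta\phi\cos\phi$ for regular grids, and any
  supplied area field overrides.
* **Delta scenarios.** A future decade is built by adding month-of-year
  increments to the present daily series (`apply_delta_scenario()`), which
  preserves within-month daily anomalies exactly — the delta method's
  purpose: impose the projected climatological shift while retaining
  observed variability. Month lookup is Gregorian; leap days use February's
  increment.

## The synthetic generators

No deposited raw data exist for this pipeline, so the `*_spec()` /
`generate_*()` module produces every input with known ground truth. Design
choices, fixed once:

* **Traces.** Post-chase uptake decays exponentially from `true_mmr` to
  `true_smr` ($\tau$ = 1.5 h default) with a 5% diel sinusoid; chamber O$_2$
  integrates that rate during 15-min closed phases (15-s sampling) and
  resets during 15-min flushes; Gaussian sample noise (sd 0.01 mg l$^{-1}$,
  an optode's precision). The default fish (5 g in a 0.5 l chamber) is
  chosen so a closed phase at MMR depletes < 20% of saturation — the
  generator must respect the normoxia window its own processing enforces;
  heavier fish in the same chamber drive phases hypoxic and get excluded.
* **Acclimation experiments.** Six groups at 17–32 °C in 3 °C steps, 12
  fish per group. MMR and SMR are drawn log-normally around their curve
  values with a common CV (default 0.15; the log-normal mean is corrected
  so CV = 0 reproduces the curves exactly). Mortality is deterministic
  whole-group removal above $T_{crit}$, matching the all-or-nothing
  survival observed in warm-acclimated groups, rather than per-fish
  stochastic survival.
* **Temperature fields.** Daily 0–30 m temperature on a 40 × 40 grid over
  8.5–16.5°E, 31.2–39.5°N for 10 years: annual mean and seasonal amplitude
  linear in latitude (23.7 ± 7.5 °C at the southern edge, 17.6 ± 4.5 °C at
  the northern), seasonal peak in mid-August, plus per-cell AR(1) daily
  anomalies (sd 0.5 °C, lag-1 correlation 0.8). These values make the
  monthly means span roughly 13.1–31.2 °C, a warm-temperate shelf-sea
  envelope whose warm half crosses the salema's $T_{crit}$ in summer — the
  regime where the two species' fates diverge. The future increment is
  drawn per month within 0.2–1.5 °C from a coarse random surface,
  bilinearly interpolated so it varies smoothly in space.
* **Occurrences.** Points sampled uniformly from cells with THS above a
  floor (default 0.62), at cell centres, so threshold derivation has an
  exact quantile oracle.

Every generator is a pure function of its spec and seed (bitwise
reproducible). What the generators *do not* emulate: coastline geometry and
bathymetry (no land mask by default), advection and upwelling, salinity or
oxygen covariates, observation error in occurrences, and spatial
correlation of daily anomalies. Passing tests therefore demonstrate the
correctness and stability of the computational chain under controlled
conditions — not that any particular real basin behaves like the synthetic
one.

## Problem sizes and determinism

The demo pipeline projects two species over two scenarios of a
40 × 40 × 3650 field in well under a minute on one CPU; unit tests use
smaller grids (≤ 12 × 12, 1–3 years) and the simulation studies use 100
seeded replicates of the 6 × 12 design. All stochastic tests fix seeds;
`run_pipeline()` writes a config hash and seed into its log and is
byte-identical under identical configurations.

## Known limitations

* Temperature is the only driver: no food, competition, dispersal,
  salinity, or oxygen limitation. CF is a statement about thermal scope,
  not a population forecast.
* Metabolic rates are not mass-corrected across body sizes; records are
  assumed to come from similarly sized juveniles.
* The MMR model's $T_m$ is an extrapolation whenever the declining limb is
  unobserved (see fitting notes); treat its standard error seriously.
* The through-origin validation $r^2$ is the uncentred version and is not
  comparable with an intercept-model $r^2$.
* `estimate_smr()`'s low quantile is biased slightly below the true
  maintenance rate when activity is rare and noise symmetric; at the
  default 48 phases per day the bias is small but nonzero.
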