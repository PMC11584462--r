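---
title: "Gap filling dendrometer records with gradient-boosted trees: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gap filling dendrometer records with gradient-boosted trees: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendrogap)
```

## The problem

Point dendrometers measure stem radius at micrometre resolution every 30
minutes. Multi-month outages — battery failures, full loggers, vandalism,
animal damage — are routine, and interpolation-based repairs are only
trusted for runs up to about 12 h (24 measuring points). dendrogap fills
*long* gaps (30 consecutive days and beyond) in the growth signal of an
individual tree using only temporal predictors, so no climate record and no
co-varying neighbour tree is required.

The pipeline is: quality control of the raw radius series, extraction of
irreversible growth with the zero-growth model, construction of a small
temporal feature matrix, and regression of growth on those features with
early-stopped gradient-boosted trees. Spline interpolation and
neighbour-tree ("network") regression are included as the baselines a
practitioner would otherwise reach for, together with a seasonal
artificial-gap benchmark that compares all of them under controlled
conditions.

## Quality control of the raw series

**Temperature screening.** Air temperature (used only as a frost guard) is
screened for plausibility: values outside [−40, 50] °C, and isolated spikes
whose difference to *both* neighbours exceeds 10 °C per 30-min step, are set
missing.

**Jump handling.** A *jump* is an abrupt sensor shift (knock, re-mounting,
electronics). `detect_jumps()` flags first differences larger than
`diff_threshold_mad` (default 10) times the MAD of all first differences —
a robust, parameter-light detector. Flagged *negative* steps that coincide
with air temperature at or below 5 °C are marked frost-guarded and never
corrected: frost-induced shrinkage is physiology, not sensor failure.
`correct_jumps()` subtracts each confirmed offset from the event onward
(offset subtraction preserves all other first differences; a `"remove"`
mode blanks the affected segment instead for data where level adjustment is
not trusted).

**Short gaps.** Missing runs of at most 24 points (12 h) flanked by
observations on both sides are filled by the straight line between the
flanking values and flagged `linear_fill`. A run of 25 points is already
left to the model-based fillers; runs touching a series end are never
interpolated.

## Zero-growth extraction and winter correction

With `M(t)` the running maximum of the cleaned radius over non-missing
points,

$$G(t) = M(t) - r(t_0), \qquad \mathrm{TWD}(t) = M(t) - r(t),$$

so that $r(t) = r(t_0) + G(t) - \mathrm{TWD}(t)$ holds exactly wherever the
radius is observed. `G` (cumulative growth) is non-decreasing and
accumulates across years; `TWD` (tree water deficit) is the reversible
shrinkage and is non-negative. Missing radius slots propagate to missing
`G`/`TWD` rather than being interpolated inside the extraction.

The zero-growth model ignores winter bark-cell degradation, which can
register as spurious cold-season "growth". `winter_correction()` cancels
positive `G` increments before day-of-year 60 and after day-of-year 304
(holding `G` at its prior level, flag `winter_corrected`) and sets negative
values missing (`negative_removed`). Cancellation rather than row deletion
keeps the series regular and non-decreasing; a `"remove"` mode deletes the
offending rows for stricter workflows.

## Features, multicollinearity, and the random baseline

The predictor set is deliberately minimal and purely temporal: day of year
(1–366; leap years run to 366 with no rescaling), calendar year (integer),
fractional hour (13.5 encodes 13:30 — the 30-min grid needs sub-hour
resolution), and, for multi-tree datasets, per-tree site constants
(unsealed area in m², capped at 144 m² = a fully unsealed surrounding;
tree height for non-urban groups). In auto mode constant-variance columns
are dropped — site constants carry no signal within a single tree, and
`year` is constant in a single-year record.

`vif_screen()` guards against multicollinearity: VIF$_j = 1/(1-R^2_j)$ from
regressing predictor $j$ on the others, iteratively removing the worst
column until all VIFs are below 5 (the conventional threshold), ties broken
toward the later-declared column for determinism. On the calendar grid the
temporal features are orthogonal by construction (max VIF ≈ 1), so
screening matters mainly when users add their own covariates through the
`extra` hook.

`add_random_feature()` appends an i.i.d. uniform column. Its permutation
importance estimates the distribution of "importance" a model can assign to
pure noise, giving every real feature an explicit null reference.

## The gap-filling model

Non-gap rows are split 80/20 into training and test subsets by stratified
sampling within every (year, hour) combination, so both subsets see every
year and every time of day; within a stratum of $n_s$ rows,
$\mathrm{round}(0.8\,n_s)$ go to training (round-half-even; strata smaller
than 5 keep at least one training row, singletons go to training with a
warning). Features are z-transformed with mean and standard deviation
estimated **on the training subset only**; the same parameters transform
the test subset and the gap rows, so normalization can never leak
information from evaluation or missing periods.

The default regressor is gradient-boosted trees (xgboost): learning rate
0.1, maximum depth 6, up to 300 rounds, with a 20 % validation subset drawn
from the training rows driving early stopping (patience 20 rounds on
validation RMSE; a `"training"` mode monitors training RMSE instead).
Early stopping is the overfitting control — hyperparameter tuning is
deliberately *not* part of the default path. The optional `tune_model()`
implements a sequential model-based search (Latin-hypercube initial design,
random-forest surrogate, candidates scored by k-fold cross-validation on
folds shared across candidates, the algorithm default always evaluated
first), but on these smooth seasonal labels it routinely confirms that the
defaults are adequate, at a large multiple of the cost. Random forest,
k-nearest-neighbours and ridge regression are registered alongside for
comparison; additional regressors plug in through `register_algorithm()`.

Fit quality is reported as RMSE and adjusted
$R^2 = 1-(1-R^2)(n-1)/(n-p-1)$ on both subsets. Gap rows are predicted
with the stored normalization; predictions outside the training feature
ranges are flagged `extrapolated`. Predictions are *not*
monotonicity-constrained: implausible fills (multi-day declines, flank
discontinuities, negative values) are surfaced by `sanity_check()` so the
analyst can reject them — hiding them would mask exactly the failure mode
that matters.

## Baselines

**Spline.** A natural cubic interpolating spline through daily-mean anchors
over five days of observations on each flank, evaluated on the gap grid.
Daily averaging suppresses half-hourly noise in the anchors; the
interpolating (unpenalized) form is the variant dendrometer toolkits apply,
and it is what produces the characteristic failure on long gaps: the gap
interior is governed by the flank derivatives, so when rapid season-onset
growth begins just beyond a gap the cubic undershoots and predicts
*decreasing* cumulative growth. That behaviour is intentionally possible
and is reported by `sanity_check()`, not suppressed.

**Network interpolation.** Assumes co-sited conspecifics share growth
variability: the best-correlated reference tree without missing values
inside the gap window is selected (correlation of growth *increments* —
cumulative levels of any two growing trees correlate trivially), the target
is regressed on it by OLS with intercept, and the regression predicts the
gap. Below `min_r = 0.5`, or without a complete reference, the result is
*not applicable* — a distinct outcome, because in practice references have
gaps of their own. The gate correlation is computed at native half-hourly
resolution by default; `cor_resolution = "daily"` compares daily growth
totals instead, which is the practical choice for extracted field records
whose half-hourly increments are sparse, unsynchronized spike trains.
`combine = "average"` averages all qualifying references instead of using
the single best.

## The synthetic study system

`simulate_tree()` generates the data the pipeline assumes, with known
truth. Cumulative seasonal growth follows a double-logistic curve: the
growth rate is the product of an onset and a reversed cessation logistic,
integrated in closed form via softplus differences and normalized per year,
so the curve is ~0 before onset, reaches half the annual amplitude at the
season midpoint, saturates exactly at the amplitude by year end, and
accumulates continuously across years. Defaults describe a temperate urban
maple: 500 µm per year between day 135 (mid-May) and day 250 (early
September) — radial growth of urban maple and plane begins weeks after
leaf-out and ceases well before leaf fall — with steepness 0.1 day⁻¹.
Tree water deficit is a diurnal sinusoid, zero overnight (21:00–09:00),
peaking mid-afternoon at up to 60 µm, tapered by the seasonal envelope.
Radius is `baseline + G − TWD` plus Gaussian sensor noise (2 µm), then
technical jumps are added cumulatively from their instants and configured
missing runs are blanked. Air temperature is seasonal + diurnal with noise,
with optional forced frost episodes; relative humidity is anticorrelated
with temperature. Every tree draws from a private RNG stream derived from
(seed, tree id), so adding trees never perturbs existing ones.

`simulate_network()` couples trees through their growth increments:
$\Delta G_i = A_i \cdot \mathrm{rate}(t)\,[\rho\,e_0(t) + (1-\rho)\,e_i(t)]$
with i.i.d. gamma multipliers (mean 1, shape 0.25). This yields monotone,
step-like "weather-burst" growth; $\rho = 1$ gives identical shapes up to
amplitude, $\rho = 0$ near-uncorrelated increments. A single-tree network
reduces to the deterministic `simulate_tree()`.

What the simulator does **not** emulate: true weather forcing (bursts are
i.i.d., so neighbouring trees share no high-frequency timing beyond the
$\rho$-coupling), precipitation or soil moisture, bark swelling and winter
cell degradation, multi-sensor drift, or year-to-year variation in onset
timing. Tests passing on this system therefore demonstrate the pipeline's
mechanics and the relative behaviour of the fillers under controlled
co-variance and phenology — not field performance on any particular
species or site.

## The artificial-gap benchmark

`make_artificial_gaps()` produces the three fixed 30-day windows per year —
start (Apr 16 – May 15), middle (Jun 1–30), end (Sep 1–30) — that probe the
growing season's onset, peak and cessation. `run_benchmark()` blanks each
window in each dataset, lets every method fill it (ML methods retrain from
scratch on the data outside the window; baselines see only local or
reference data), and scores RMSE against the withheld values on the
half-hourly grid. With 16 datasets (12 individual trees + 4 grouped) over
2019–2023 this yields 15 windows per dataset and 240 trained models.
Grouped datasets train on an hourly grid (`thin = 2`), the conventional
resolution for multi-tree compilations, while predictions always cover the
half-hourly gap rows.

Method differences are assessed nonparametrically: the Friedman chi-square
test on within-block ranks across (dataset, window) blocks, and the
two-sided Mann–Whitney U test for pairs (exact by enumeration for
tie-free samples of total size ≤ 12; normal approximation with tie and
continuity correction otherwise). `friedman_rmse(exact = TRUE)` enumerates
the full permutation distribution for small designs, where the chi-square
approximation is anti-conservative. P-values are reported, never enforced,
and no multiple-testing correction is applied.

Permutation feature importance is the mean drop in $R^2$ over 50
permutations of one raw feature column (re-normalized with the training
parameters each time), by default on the test rows. Values exceed 1 when
permuted models fall to negative $R^2$ — which is exactly what happens to
day-of-year on strongly seasonal growth.

## What the benchmark shows on synthetic data, and why

Two structural results are worth understanding before interpreting any
benchmark table produced by this package.

First, a boosted-tree model asked to predict inside a blanked window is
extrapolating into a region of feature space with no training support for
that year: its fill is approximately constant at a flanking level, so its
gap error scales with the growth that occurs *within* the window. It is
therefore most accurate at the start and end of the growing season (little
in-window growth) and weakest mid-season — the mid-season window is the
hardest for every method.

Second, the spline's gap interior is driven by flank derivatives. When the
seasonal onset erupts near the end of the start window and growth proceeds
rapidly beyond it, the cubic undershoots below the flat pre-onset level —
decreasing, even negative, predicted growth — and the ML fill's flat
bridge wins robustly. When the onset instead sits mid-window, a spline
tracks the smooth rise better than a flat bridge can, and the comparison
inverts. The package's acceptance checks exercise the first regime
(onset day 136, steepness 0.35, bursty growth), which is the regime the
start-window evaluation is designed to probe.

## Numerical choices and degenerate inputs

* Timestamps are timezone-naive local standard time (held as UTC POSIXct);
  DST is not modelled. The 30-min grid is strictly enforced; gaps are
  explicit `NA` slots, never skipped rows.
* Radius is micrometres internally; readers convert from a declared unit.
  CSVs are comma-separated with ISO-8601 timestamps, empty fields for
  missing values, and full double precision, so write→read is the identity.
* The MAD scale in jump detection falls back to the standard deviation
  when the MAD is zero (e.g. a locally constant series).
* `zero_growth()` requires a non-missing first value (trim leading gaps
  first) and refuses all-missing input. The reconstruction identity is
  exact up to one double-precision rounding of the two subtractions.
* Stratified splitting, cross-validation folds, validation subsets,
  permutations and all simulator draws derive their streams from explicit
  seeds through a 31-bit string-keyed hash; every pipeline stage is
  bit-reproducible from (configuration, seed), and library calls restore
  the caller's RNG state.
* Model-filled slots are exempt from the growth-series monotonicity
  invariant (fills may legitimately decrease; `sanity_check()` reports
  them). Observed slots are never overwritten by any filler.

## Problem sizes used in the shipped checks

The package's own test suite and the `scripts/acceptance.R` report run the
full 16-dataset × 15-window benchmark (240 boosted-tree fits, about five
minutes on one core at 200-round budget), a five-seed method comparison on
two-year abrupt-onset trees, a 1000-series zero-growth property sweep, and
50-permutation feature-importance runs — sizes chosen so the entire
evidence base regenerates from scratch in minutes while still exercising
the design at the full multi-year, half-hourly scale.

## Known limitations

* Gap predictions from tree ensembles are piecewise-constant in unobserved
  feature regions; they will not reproduce fine within-gap dynamics, only
  the level. For gaps spanning high-growth periods, inspect the
  `sanity_check()` output and consider the baselines.
* The zero-growth label means the method fills *growth*, not raw radius;
  reconstructing raw radius inside a gap additionally requires a water-
  deficit model, which is out of scope.
* `year` enters as an integer, so models cannot generalize beyond the
  observed year range without extrapolation (flagged, but still a guess).
* The network baseline's correlation gate cannot distinguish shared
  seasonality from shared high-frequency variability on extracted series;
  choose `cor_resolution` to match the question being asked.
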