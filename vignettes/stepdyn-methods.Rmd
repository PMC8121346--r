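---
title: "Methods: sudden gains/losses and dynamic-complexity early warning signals in daily step counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sudden gains/losses and dynamic-complexity early warning signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

stepdyn implements an idiographic (within-person) analysis of long daily
step-count series from wearable activity monitors. The analysis has three
stages: (1) detect *sudden gains and losses* — abrupt shifts of a person's
daily step level to a new stable level — by recursive partitioning of each
series on the day index; (2) compute *dynamic complexity*, a windowed
fluctuation statistic, as a candidate *early warning signal* of imminent
shifts; and (3) estimate, by discrete-time multilevel event-history analysis,
whether locally elevated complexity predicts a gain or loss in the next few
days. A synthetic cohort generator with known ground truth makes every stage
testable end to end without access to any particular study's data.

This vignette documents the statistical procedures, the conventions and
numerical choices behind them, and what the bundled tests do and do not
establish.

## Data model and preparation

The atomic input is one participant's day-indexed series of step counts on a
dense calendar grid: absent days are explicit missing entries, never silent
gaps. `read_step_series()` densifies long-format CSV input (columns
`participant_id`, ISO-8601 `date`, `steps`, optional `wear_minutes`) and
rejects duplicate person-days, non-ISO dates, and negative counts outright.

Three preparation rules are applied, in this order:

1. **Wear-time validity** (`apply_wear_validity()`): a day is trusted only
   with at least 600 minutes of valid device wear; otherwise its count is set
   to missing. The 600-minute floor is the conventional validity cut for
   full-day wear. When the data have no wear channel (synthetic cohorts), the
   filter is a warning no-op.
2. **Inclusion** (`check_inclusion()`): a participant enters the analysis set
   with at least 90 days of observation and *strictly less than* 20% missing
   days. The missing fraction is computed after the validity filter, so
   invalid days count as missing; applying validity first is the stricter of
   the two possible orders and is the package default (the order is exposed
   through the function arguments).
3. **Imputation** (`impute_kalman()`): missing days are replaced by the
   smoothed state of a local-level structural state-space model (random-walk
   level plus observation noise) fitted per participant by maximum
   likelihood (`StructTS`). The local level is the smallest state-space model
   consistent with Kalman-smoother imputation for a slowly drifting daily
   series, and it is deterministic given the data — no draws, no ARIMA order
   search. Imputed values are clipped at zero; observed values are never
   altered. Leading and trailing gaps are back/forecast with the boundary
   smoothed level, which is exact for a random-walk level. If the variance
   optimizer fails (e.g. a constant series), the fallback is linear
   interpolation with a warning.

The chain is idempotent: re-running `prepare_steps()` on its own output
changes nothing.

Imputation quality has a sharp internal benchmark: on simulated AR(1) series
with known parameters, the test suite compares the local-level smoother's
masked-day RMSE against the exact conditional-mean (Gaussian bridge)
imputation at the true parameters — the best any method can do. The
local-level model is deliberately misspecified there, and its mean RMSE still
sits within about 5% of the oracle's across replicates; the test requires
within 10%.

## Detecting sudden gains and losses

### Segmentation

`segment_series()` fits a piecewise-constant model to the imputed series by
CART-style recursive binary splitting with the study day as the only
predictor. At each node, every admissible split day is scanned and the one
minimizing the summed within-child squared error is chosen. A split is
accepted only if

* both children span at least `min_segment_days` (default 7) days, and
* the SSE reduction is at least `complexity_parameter` (default 0.01) times
  the *root* SSE.

Because the predictor is one-dimensional, the scan is exhaustive, so the
greedy recursion *is* the best-split search at every node; the test suite
verifies equality with an independently coded exhaustive-search oracle on
random series up to 200 days. Ties between candidate split days are broken
toward the earliest day, making the segmentation deterministic. The 0.01
acceptance value is the canonical default of the CART family; both knobs are
exposed in `detection_params()`.

One convention deserves emphasis: the acceptance rule is applied *per split*
during growing (pre-pruning). Cost-complexity pruning — as in `rpart` — can
retain a pair of nested splits whose joint improvement passes the threshold
even though neither passes alone, and therefore sometimes yields a superset
of our breakpoints on noisy series. On clean, well-separated shifts the two
coincide (this is cross-checked against `rpart` in the tests). The per-split
rule was chosen because it is the one that makes "accept a split" a local,
reproducible decision.

### Classification

`classify_transitions()` turns the segmentation into events: for each
adjacent pair of segments, a *sudden gain* (upward) or *sudden loss*
(downward) is recorded when the absolute level difference reaches
`threshold_frac` (default 0.30) of the participant's study-period **median**
daily steps. The median, not the mean, anchors the criterion because daily
step counts are right-skewed within persons. For a participant with a median
of 7000 steps/day the default cut is therefore 2100 steps/day. The comparison
is inclusive (`>=` the cut); with continuous fitted levels the boundary case
is measure-zero, and the convention only matters for constructed examples.

The event day is the *first day of the new regime* — the convention required
for the "complexity in the days preceding" predictor to be well defined.
Segment levels are segment means (regression trees predict means), even
though the criterion is scaled by the median.

The 7-day minimum segment length operationalizes the stability requirement —
a qualifying shift must be preceded and followed by at least a week of the
new level — and structurally controls weekday/weekend cycles, since every
regime spans at least one full week. A consequence worth knowing: a spike
shorter than the stability window is rejected only through *dilution*. Any
segment containing it spans at least 7 days, so its fitted mean is pulled
toward the surrounding level; a 3-day spike of +60% dilutes to about +26% of
the median and produces no event, while a 5-day spike of +60% dilutes to
about +43% and still qualifies. High-variability periods are thus not
categorically unclassifiable — only those whose week-scale average stays
under the threshold.

Event counts are monotone in the threshold by construction (the segmentation
does not depend on it): every event at ±40% is an event at ±30%, and every
event at ±30% is one at ±20%. The tests assert this nesting on fixed
cohorts.

## Dynamic complexity and the early-warning predictor

Dynamic complexity is the product `C = F × D` of two statistics computed on a
backward moving window (default `window_days = 7`), following the
fluctuation-and-distribution construction used in the psychotherapy
early-warning literature.

**Fluctuation intensity `F`** captures the amplitude and frequency of
direction changes. The window is partitioned into maximal monotone runs,
delimited by direction reversals; a zero first-difference terminates a run
(ties are not part of a trend — a convention point, flagged as such in the
code). A run spanning amplitude $a_k$ over $d_k$ day-intervals contributes
$a_k / d_k$, and

$$F = \frac{\sum_k a_k / d_k}{s\,(m - 1)},$$

where $m$ is the window length and $s$ the attainable scale range. `F` is 0
for a constant window and exactly 1 when the series alternates between the
scale extremes every day (each of the $m-1$ runs contributes $s/1$).

**Distribution measure `D`** captures how evenly the window's values cover
the attainable range. With the window sorted ascending, every index span is
compared against the spread of an ideal uniform grid over the scale; only
*shortfalls* (empirical spread below uniform spread) accumulate:

$$D = 1 - \frac{\sum_{c=1}^{m-1}\sum_{i=1}^{m-c}
  \max\{0,\; c\,s/(m-1) - (y_{(i+c)} - y_{(i)})\}}
  {\sum_{c=1}^{m-1} (m-c)\, c\, s/(m-1)}.$$

`D` is 0 for a constant window and 1 for values exactly uniformly spaced
across the full scale. Both statistics live in $[0,1]$, are invariant to
joint linear rescaling of the data and the scale bounds, and are invariant to
time reversal of the window; all three properties are asserted over hundreds
of random windows in the tests, and both statistics are checked to $10^{-12}$
against independently coded brute-force implementations.

**Conventions.**

* *Scale bounds*: per-participant observed min/max of the full imputed
  series (`scale = "participant"` in `complexity_params()`), matching the
  idiographic anchoring of `D` to "the range of possible values within the
  time series"; a fixed device-wide scale is available as an option. A
  degenerate scale (min = max) yields `F = D = 0` with a warning.
* *Window alignment*: the window for day $n$ is the `window_days` values
  ending **at** $n$ (days $n-6 \dots n$ for a 7-day window). Verbal
  "between day $n-7$ and day $n$" phrasings are off-by-one ambiguous; this
  convention makes the window length equal `window_days` exactly.
* *Warm-up*: days before the first full window have undefined (`NA`)
  complexity — never zero.

**Local dynamic complexity (LDC)**, the early-warning predictor, is the
maximum of `C` over the `ldc_lag_days` (default 3; sensitivity 2 and 4) days
*strictly preceding* a day; the day itself is excluded so the predictor is
strictly prospective. LDC at lag 4 dominates LDC at lag 2 pointwise (a
maximum over a superset), which the tests assert.

## Discrete-time multilevel event-history analysis

`build_event_table()` lays out one record per participant-day with a defined
LDC. Each record carries the binary outcome (a classified event occurs that
day), `time` (the progressive study day — hazards may drift over a long
study), and `duration` — the number of days since the participant's most
recent prior event, or since study start if none. The duration clock is
1-based: 1 on the first study day and on the day after an event. It resets at
*any* classified event, gain or loss, in all models — events of either
direction end a stable regime, so both are renewal points for the "time since
last shift" clock. Censored participants (no events) contribute all their
at-risk days with outcome zero. The only exclusion is the warm-up: days
without a defined LDC (the first `window_days + ldc_lag_days - 1` days of
each series) never enter the table.

`fit_event_model()` fits the hazard model by mixed-effects logistic
regression (lme4, Laplace approximation):

```
outcome ~ time + duration + ldc + (1 + time + duration + ldc || participant_id)
```

with a random intercept and mutually *uncorrelated* random slopes (diagonal
random-effects covariance — the `||` syntax) for all three predictors: the
maximal structure the person-day design supports. Continuous predictors are
z-scored over all included records (grand standardization), so each
coefficient is a per-1-SD log-odds and `OR = exp(beta)` is the per-1-SD odds
ratio. Grand rather than within-person standardization is used because a
single pooled "per 1 SD" effect is the estimand; the choice is exposed via
`standardize = FALSE` plus pre-scaled inputs.

Three framings are fitted: *both* (any event), *gains only* and *losses
only*. The single-direction models keep only participants with at least one
event of that direction, code the outcome as that direction alone, and leave
other-direction event days in the risk set with outcome zero. This subsetting
reproduces the participant-count pattern N(both) ≥ N(gains-only) and
N(both) ≥ N(losses-only).

**Estimation conventions.** The optimizer is `bobyqa` with derivative checks
off — fixed settings, so the fit is deterministic given the data. When the
maximal model is singular (a slope variance estimated at zero), the slope
with the smallest variance is dropped and the model refit, with a message;
the random intercept is always retained. Confidence intervals are Wald by
default; `compute_odds_ratios(..., method = "profile")` computes likelihood
profile intervals by constraining each coefficient in turn through an offset,
refitting, and bisecting the profiled deviance for the points where it rises
by the $\chi^2_1$ 95% quantile above the minimum. Profiling falls back to
Wald with a warning when the profiled deviance does not cross the cutoff, and
the method actually used is recorded in the output (`ci_method`). At
person-day sample sizes the likelihood is near-quadratic and the two agree
closely (asserted within 5% in the tests); the point estimates — the odds
ratios themselves — do not depend on the CI method.

## The synthetic cohort generator

`simulate_cohort()` generates ground-truthed cohorts whose default parameters
emulate a long wearable study of about 151 adults: series length normal with
mean 226 days clamped to [107, 320]; per-participant base level normal with
mean 10,120 steps/day (chosen so the cohort mean daily count lands near 9,687
after the weekend factor); instantaneous level transitions at a rate of 0.95
per 30 days with at least 10 days between them (about 6 transitions per
participant, mean spacing near 31 days); regime levels alternating above and
below the base by a uniform 17–31% offset, so consecutive levels differ by
roughly 4,900 steps on average; a ×0.85 weekend level factor; mean-one
lognormal daily noise with log-SD 0.25 (daily counts are right-skewed);
and per-participant missing fractions with mean 8.8% (about 20 days) in
geometric gap runs of mean length 2 days, capped at 27%. Transitions are
instantaneous level shifts rather than ramps — the sudden-gain/loss
construct under study. Within-regime noise is independent by default; an
AR(1) coefficient is exposed (`ar1`, default 0) rather than guessing an
autocorrelation no one has estimated.

The early-warning structure is planted directly: the `precursor_window`
(default 5) days before each transition have their noise SD multiplied by a
direction-specific factor — 2.0 before losses, 1.0 before gains by default.
This loss-specific variance inflation is the generative analogue of the
asymmetric empirical finding the pipeline is designed to detect: elevated
pre-transition fluctuation predicting losses but not gains.

Determinism is strict: identical config and seed give identical cohorts, with
per-participant seeds derived reproducibly from the master seed so
participants are independent but reproducible.

**What the generator does not emulate.** Real wearable data have device
artifacts (non-integer sync totals, duplicated days), informative
missingness (non-wear correlated with low activity), gradual ramps as well as
abrupt shifts, seasonal and holiday structure, and measurement error
correlated with activity type. Passing tests on synthetic cohorts therefore
establish that the pipeline recovers what it is designed to recover under its
own assumptions — not that those assumptions hold in any particular dataset.

## Test calibration and problem sizes

The test suite checks detection recovery at two noise levels. Noise-free
injected shifts must be recovered breakpoint-exactly. Under *calibrated*
noise — lognormal log-SD 0.10, no precursor inflation — precision and recall
must both reach 0.9 for shifts of at least 1.5× the threshold, with
breakpoints matched within ±2 days. The calibrated level is the regime in
which near-perfect recovery is statistically possible, so the assertion tests
algorithmic correctness; under the generator's full default noise (log-SD
0.25 plus precursor inflation) single-day localization is not statistically
identifiable to ±2 days and measured recall is around 0.7 — a property of
the signal-to-noise ratio, not of the implementation.

Model-recovery simulations use 50 replicates each: null coverage (50
participants × 200 days; the LDC interval must cover OR = 1 in at least 90%
of replicates) and effect recovery (true per-SD log-odds +0.4; mean estimate
within ±0.1). The end-to-end signature check runs the full pipeline on ten
30-participant cohorts with loss-only precursor inflation and requires the
losses-model LDC OR above 1, and the gains-model OR not significantly above
1, in at least 80% of replicates. These sizes keep the whole suite in the
tens of minutes on one CPU while leaving the Monte-Carlo margins comfortable.

## Known limitations

* Level shifts only: trend (slope) changes and within-day dynamics are out of
  scope; a ramp is approximated by a staircase of level shifts.
* The complexity statistic is univariate; multi-indicator extensions are not
  implemented.
* The per-split acceptance rule can differ from cost-complexity-pruned trees
  on weak nested splits (see above).
* Whether complexity should be computed on imputed or raw-with-gaps series is
  a genuine modelling choice; this package computes it on imputed series,
  consistent with imputation being the first preparation stage. Imputed
  stretches are smoother than observed ones and locally depress `F`.
* The event-history model conditions on detected events as if they were
  observed outcomes; detection error propagates into the association
  estimates and is not corrected for.
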