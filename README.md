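# stepdyn

Idiographic analysis of daily walking behavior from wearable step counts:
detection of **sudden gains and losses** (abrupt within-person shifts of the
daily step level to a new stable level), computation of **dynamic
complexity** as an early-warning signal, and **discrete-time multilevel
event-history models** estimating whether locally elevated complexity
predicts an imminent gain or loss.

The package is for researchers working with long (months-scale) per-person
daily step-count series — e.g. from activity trackers in behavioral
interventions — who want to move beyond aggregate before/after comparisons
and characterize *when* and *how abruptly* each individual's behavior
reorganizes, and whether those reorganizations announce themselves.

## The method

**Sudden gains/losses.** Each participant's imputed daily series is segmented
by CART-style recursive partitioning on the study day (exhaustive best-split
search at every node, minimum segment length 7 days, split accepted when the
SSE reduction is at least 1% of the root SSE). An adjacent-segment level
shift is classified as a sudden gain (up) or loss (down) when

|post level − pre level| ≥ 0.30 × median(participant's daily steps),

so a participant with a median of 7000 steps/day has a cut of 2100 steps/day.
The 7-day minimum enforces the stability requirement (a week of the new level
on both sides) and spans weekday/weekend cycles.

**Dynamic complexity.** For each day *n*, the score C = F × D is computed on
the backward 7-day window ending at *n*. F (fluctuation intensity) sums
amplitude-per-day over maximal monotone runs, normalized so that a window
alternating between the scale extremes every day gives F = 1. D (distribution
measure) compares the sorted window against an ideal uniform grid over the
participant's observed range, accumulating only shortfalls; D = 1 for perfect
uniform coverage. Both lie in [0, 1]. The early-warning predictor, **local
dynamic complexity (LDC)**, is the maximum of C over the 3 days strictly
preceding each day (lags 2 and 4 as sensitivity settings).

**Event-history model.** On the person-day grid, the daily hazard of an event
is modelled by mixed-effects logistic regression (lme4):

```
event ~ time + duration + ldc + (1 + time + duration + ldc || participant_id)
```

with z-scored predictors, a random intercept and uncorrelated random slopes;
`duration` is the days since the participant's previous event (censoring and
repeated events are handled by this clock). Odds ratios are per 1 SD, with
Wald or likelihood-profile confidence intervals. The model is fitted three
ways: any event, gains only, losses only.

A synthetic cohort generator (`simulate_cohort()`) produces ground-truthed
cohorts — piecewise-stable series with known breakpoints, weekend effects,
lognormal noise, configurable pre-transition variance inflation, and realistic
missingness — so the whole pipeline is testable offline. See the methods
vignette (`vignettes/stepdyn-methods.Rmd`) for conventions and design
decisions.

## Worked example

```r
library(stepdyn)

cfg <- cohort_config(n_participants = 20, seed = 42)
res <- run_pipeline(config = cfg, quiet = TRUE)
res
#> <stepdyn_pipeline> 20 participants, 154 events (85 gains / 69 losses)
#>   mean length 240 d, mean daily steps 9479, mean |delta| 4673 steps, mean gap 27.0 d
#>   model both   LDC OR = 1.262 [1.104, 1.442]
#>   model gains  LDC OR = 0.489 [0.317, 0.757]
#>   model losses LDC OR = 1.694 [1.471, 1.950]
```

The 20 simulated participants wore their (synthetic) tracker for 240 days on
average and experienced 154 sudden gains or losses with a mean magnitude of
about 4700 steps/day. The default generator plants extra variance in the 5
days *before* losses only, and the models recover exactly that asymmetry: one
SD more local dynamic complexity raises the odds of a sudden loss in the next
3 days by ~69% (OR 1.69), while gains are not positively predicted.

Per-model detail comes through broom:

```r
tidy(res$models$losses, exponentiate = TRUE)
#> # A tibble: 3 × 5
#>   term     estimate conf.low conf.high ci_method
#>   <chr>       <dbl>    <dbl>     <dbl> <chr>
#> 1 time        0.918    0.714      1.18 wald
#> 2 duration    1.11     0.869      1.42 wald
#> 3 ldc         1.69     1.47       1.95 wald

head(res$events, 3)
#> # A tibble: 3 × 8
#>   participant_id date         day direction pre_level post_level delta_steps
#>   <chr>          <date>     <int> <chr>         <dbl>      <dbl>       <dbl>
#> 1 P001           2019-06-18    16 gain          5682.      8870.       3188.
#> 2 P001           2019-07-18    46 loss          8870.      6006.      -2864.
#> 3 P001           2019-08-13    72 gain          6006.      8138.       2131.
```

`plot_step_series(res$steps, res$events)` draws the series with the fitted
segmentation and event markers; `plot_complexity_trace(res$trace)` stacks the
complexity trace beneath the steps. `run_sensitivity_grid()` re-runs the
analysis over thresholds {20%, 30%, 40%} × LDC lags {2, 3, 4} × outcome
framings and returns a tidy grid of event counts and odds ratios.

To analyze real data instead of a simulation, pass a long-format CSV through
`read_step_series()` and hand the result to `run_pipeline(data = ...)`.

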