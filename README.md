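# rangewatch

Monitoring long-term degradation of semi-arid rangelands from satellite-style
reflectance time series, and asking the question that decides how to manage
them: when a landscape ends up degraded, did it get there because it **lost
resistance** (it declines more than its neighbours during drought shocks) or
because it **lost recovery** (it declines like everyone else but fails to
bounce back)? The distinction matters — promoting resistance and promoting
recovery call for different interventions — and it can be read off a
two-decade time series of a per-pixel *bare-ground index* (BGI).

The package is aimed at quantitative ecologists and remote-sensing analysts.
It ships a fully synthetic savanna world with controllable resistance and
recovery, so that every stage of the analysis is testable against known
ground truth, and it accepts any tabular per-pixel data with the same schema.

## What it computes

**Bare-ground index.** From multi-band reflectance scenes (Blue/Red/NIR/SWIR)
it computes NDVI, EVI, MSAVI and a four-band bare-soil index

```
BSI = ((SWIR + Red) - (NIR + Blue)) / ((SWIR + Red) + (NIR + Blue)),
```

masks cloudy pixels (score < 10% kept), fills short temporal gaps (runs of
1-3 scenes) by linear interpolation, and builds seasonal composites over the
November-October window. Per pixel and year the predictors are the composite
mean, the magnitude and phase of an annual harmonic `a0 + a1 cos 2πt +
b1 sin 2πt` fitted per index, and May-April accumulated rainfall — ten
predictors. Bare-ground percent from point-intercept field plots
(`Binomial(100, b)`) is the response, modelled as `log(x + 1)`; random
forest, nu-SVR and gradient boosted trees are compared by repeated random
cross-validation (10 repeats, 75/25) inside a 75% training partition and
evaluated once against a 25% holdout, with the best holdout RMSE selected.
Predictions are back-transformed, z-scored against the 2016 map, and min-max
normalized to [0, 1] across all pixel-years.

**Resistance vs recovery.** Scores are aggregated to ~200 m cells by block
median, cells are ranked into *most/medium/least degraded* tertiles by their
median normalized score over the final three years, and shock years are the
four largest year-over-year increases of the landscape median. For each
shock year `s`, resistance is the per-cell change `Δs = score_s −
score_{s−1}` and recovery the following year's change, in absolute units
(`−Δrec`) and relative to the shock (`−Δrec / Δs`; 1 = total recovery, 0 =
none, < 0 = continued decline, > 1 = net improvement). Classes are compared
with two-way ANOVAs, marginal means and Tukey contrasts, and a mechanism
verdict (`loss_of_resistance` / `loss_of_recovery` / `mixed` /
`indeterminate`) is derived from the per-year most-vs-least contrasts.

**Drivers of the long-term trend.** Each cell's rainfall-adjusted rate is
the year coefficient of `score ~ 1 + year + rainfall`, and the rates are
regressed on human density, livestock density, mean annual rainfall and
land-use designation (CCRO/WMA/NP vs unprotected) in a hierarchical model
`rate = Xβ + u + e` with a Matérn-type (exponential) spatial random field
`u`, estimated by restricted maximum likelihood over an eigendecomposition
of the correlation matrix, with leave-one-out PIT calibration checks.

## Worked example

Simulate a landscape whose degradation is driven by loss of resistance, and
ask the package which mechanism it sees:

```r
library(rangewatch)
library(dplyr)

cfg   <- world_config(grid_rows = 84, grid_cols = 84, seed = 42)
world <- simulate_world(cfg)

scores <- world$cover |>
  rename(bg_score = b_true) |>
  aggregate_to_coarse("bg_score", block = cfg$block) |>
  normalize_scores()

res <- assess_resilience(scores, n_boot = 200)
res
#> <rw_resilience>
#>   shock years: 2002, 2006, 2011, 2016
#> <rw_verdict> loss_of_resistance
#>   shock years with larger decline in most-degraded class: 4/4
#>   recovery years with smaller recovery in most-degraded class: 0/4
```

The verdict is read from the per-class medians: in all four detected shock
years the eventually most-degraded tertile declined more (lower resistance),
while its absolute recovery in the following years was never significantly
smaller — exactly the loss-of-resistance signature. `tidy(res)` returns the
class-by-year medians with bootstrap CIs behind the figures:

```r
tidy(res)
#> # A tibble: 24 × 7
#>   metric      year class  median ci_lo ci_hi     n
#>   <chr>      <int> <fct>   <dbl> <dbl> <dbl> <int>
#> 1 resistance  2002 least   0.361 0.341 0.383    48
#> 2 resistance  2002 medium  0.380 0.361 0.395    48
#> 3 resistance  2002 most    0.436 0.419 0.452    48
#> ...
```

The spatial covariate model recovers planted drivers of the long-term rate,
flagging effects whose 95% interval excludes zero:

```r
d   <- simulate_trend_data(rows = 24, cols = 24, seed = 42)
fit <- fit_spatial_model(d)
tidy(fit)
#> # A tibble: 7 × 6
#>   term            estimate std.error    lower    upper supported
#> 1 (Intercept)      0.622     0.00652  0.609    0.634   TRUE
#> 2 human            0.0134    0.00162  0.0102   0.0165  TRUE
#> 3 rainfall        -0.0540    0.00171 -0.0573  -0.0506  TRUE
#> 4 livestock        0.0152    0.00152  0.0122   0.0181  TRUE
#> 5 designationCCRO  0.00296   0.00576 -0.00833  0.0142  FALSE
#> 6 designationWMA  -0.0146    0.00480 -0.0240  -0.00517 TRUE
#> 7 designationNP   -0.0315    0.00602 -0.0433  -0.0197  TRUE
```

Drier areas degrade faster (negative rainfall effect), human and livestock
pressure accelerate degradation, national parks and wildlife management
areas slow it, and community certificates (CCRO) are indistinguishable from
unprotected land. `autoplot(fit)` draws the forest plot;
`run_pipeline(pipeline_config(), outdir)` runs the whole chain —
simulation, scene rendering, feature building, BGI training, prediction,
resilience analysis, trend regression — and writes every artifact as CSV/
JSON with a hashed manifest.

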