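# rangemargins

Quantifying species range-margin shifts from presence–absence surveys.

`rangemargins` is for ecologists who need to ask, from a handful of
heterogeneous survey campaigns, *when did a species' range edge start
moving, and how fast is it moving now?* It was built around the
stasis-then-expansion dynamics typical of recovering carnivore
populations (the motivating case is a riverine mesocarnivore
re-expanding northward after a historical contraction), but applies to
any georeferenced detection/non-detection series with a definable range
margin.

## What it computes

**Margin statistics.** Survey records (site, planar x/y in km, period,
detected 0/1) are resampled to a common grid (one detection and one
non-detection at most per 10-km cell, so occurrences are never masked),
the range center is fixed as the centroid of a reference period's
occurrences, and each period's range margin is the set of occurrences
farthest from that center — by a strict 95th-percentile rule for
range-wide surveys, or top-*k* for periphery-restricted ones. A
minimum enclosing circle around each period's margin sites delimits the
range periphery, whose detection/non-detection records form the
occupancy series.

**Trend models.** Five candidate mean structures for distance-from-center
(Gaussian) or occupancy (binomial, logit link) against year *t*:

| form | mean structure |
|---|---|
| constant | β₀ |
| linear | β₀ + β₁t |
| quadratic | β₀ + β₁t + β₂t² |
| left-horizontal | β₀ + γ(t − ψ)₊ |
| two-slope | β₀ + β₁t + γ(t − ψ)₊ |

where (t − ψ)₊ = max(0, t − ψ) is the hinge and ψ the breakpoint year,
estimated by iterative linearization with a profile-likelihood
initialization and certification. The pre- and post-breakpoint slopes
are reported as `year` and `year_right` = β₁ + γ. A pseudo-score test
(averaged hinge regressor over K candidate breakpoints, with a
parametric-bootstrap cross-check) tests for the existence of a
breakpoint without estimating ψ under the null.

**Model selection.** Small-sample AICc = 2·NLL + 2k + 2k(k+1)/(n−k−1)
with Akaike weights; k counts mean-structure parameters including ψ,
plus one for the Gaussian residual variance.

**Synthetic data.** `simulate_margin_series()`,
`simulate_occupancy_series()` and `simulate_spatial_survey()` generate
series and full spatial snapshots with known ground truth
(flat-then-linear distance trajectories, rise-then-fall occupancy on
the logit scale), so the whole pipeline can be validated by parameter
recovery.

## Worked example

Simulate a five-period survey (1985, 2003, 2013, 2019, 2021) whose
margin holds at ~162 km from the range center until 2006 and then
expands at 5.48 km/year (residual SD 17.6 km), then run the analysis:

```r
library(rangemargins)

sv      <- simulate_spatial_survey(survey_design(), seed = 11)
ctr     <- range_center(sv, reference_period = "1985")
margins <- select_margins(sv, ctr, rule = "auto")
series  <- build_margin_series(margins, ctr)

fit_trend(series, "left_horizontal")
#> <trend_fit> left_horizontal / gaussian, n = 30
#>   breakpoint year: 2007.07 (SE 1.743, 95% CI 2003.5-2010.6)
#>   NLL = 118.2434, np = 3, k(AICc) = 4, converged: TRUE
#> # A tibble: 3 × 5
#>   term        estimate std.error conf.low conf.high
#>   <chr>          <dbl>     <dbl>    <dbl>     <dbl>
#> 1 (Intercept)   154.       3.79    146.      162.
#> 2 hinge           6.21     0.911     4.34      8.08
#> 3 year_right      6.21     0.911     4.34      8.08
```

The fitted breakpoint (2007.1) and post-breakpoint expansion rate
(6.2 km/yr, 95% CI 4.3–8.1) recover the planted 2006 / 5.48 within one
realization's noise. Ranking the full candidate suite:

```r
compare_trends(series)
#>   model            aicc delta_aicc   weight   nll    np     k
#> 1 quadratic        244.       0     0.599     117.     3     4
#> 2 left_horizontal  246.       1.75  0.250     118.     3     4
#> 3 two_slope        247.       2.75  0.152     117.     4     5
#> 4 linear           270.      25.6   1.66e-6   132.     2     3
#> 5 constant         308.      63.9   8.09e-15  152.     1     2

pscore_test(series)
#>   statistic     p_value     K null_form family
#> 1      6.67 0.000000367     8 linear    gaussian
```

The monotone forms get essentially zero weight and the pseudo-score
test rejects "no breakpoint" decisively — the expansion did not proceed
at a constant rate from 1985. The occupancy side behaves the same way:

```r
occ <- simulate_occupancy_series(survey_design(), occupancy_params(), seed = 11)
ofit <- fit_trend(occ, "two_slope")       # breakpoint year: 2019.0
predict_trend(ofit, x_new = c(1985, 2019, 2021))
#>    year estimate conf.low conf.high
#> 1  1985    0.101   0.0369     0.247
#> 2  2019    0.723   0.579      0.832
#> 3  2021    0.160   0.0614     0.357
```

`autoplot()` draws any fitted trend with its confidence band, and
`tidy()`/`glance()` give broom-style tabular summaries.

## Limitations

- Planar projected coordinates only (project to an appropriate UTM zone
  first); no CRS engine, no map rendering.
- One breakpoint per model; no detection-probability (imperfect
  detection) layer — occupancy is the naive detection proportion.
- See `vignettes/range-shift-methods.Rmd` for the estimation details,
  simulation design, and known edge cases.
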