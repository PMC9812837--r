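---
title: "Methods: quantifying range-margin shifts with segmented trend models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying range-margin shifts with segmented trend models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rangemargins)
```

## The problem

A species recovering from a historical range contraction often shows a
long *stasis* phase — the range edge does not move while local density
(occupancy) builds up — followed by an abrupt switch to sustained
expansion once edge populations are large enough to export
long-distance dispersers (the stratified-diffusion picture). Detecting
that switch, dating it, and estimating the post-switch expansion rate
from a handful of heterogeneous historical surveys is the estimation
problem this package addresses.

The data are georeferenced detection/non-detection records from a few
survey periods spanning decades. Two derived series carry the signal:

* the **margin-distance series** — for each period, the distances (km)
  of the most peripheral occurrences from a fixed reference range
  center (the centroid of a reference period's occurrences); Gaussian
  response;
* the **periphery occupancy series** — detection/non-detection of all
  sites falling inside the minimum enclosing circle of each period's
  margin occurrences; Bernoulli response on the logit scale.

## From records to series

**Grid resampling** (`resample_to_grid()`). Surveys of different
vintage differ in spatial effort; retaining at most one record per
10-km grid cell and period equalizes them. Detections and
non-detections are resampled *independently* per cell, so an occurrence
can never be erased by a co-located non-detection. The draw is seeded
and stable under row permutation (records are sorted before sampling).
Cell size (default 10 km, the European atlas convention) and the grid
origin are configurable.

**Range center** (`range_center()`). The coordinate-wise mean of the
reference period's detections. All distances, in every period, are
measured from this one fixed point, so the series measures displacement
of the edge relative to a common origin rather than period-specific
geometry.

**Margin selection** (`select_margins()`). Two rules, reflecting two
survey geometries:

* *percentile* — occurrences whose distance strictly exceeds the
  q-quantile (default q = 0.95) of all of that period's occurrence
  distances, optionally restricted to sites poleward of the center
  (`northern_only`, default TRUE). The quantile is the
  linear-interpolation type (R's default, type 7) and inclusion is
  strict; both choices are arbitrary but must be fixed for
  reproducibility, and both are exposed as parameters. Distances are
  pooled over all of the period's occurrences before the quantile is
  taken; the directional filter applies only to selection (the
  alternative reading — quantile over northern sites only — is
  expressible by pre-filtering the input).
* *top-k* — the k most distant occurrences, for periphery-restricted
  surveys where a range-wide percentile is undefined. Ties are broken
  by `site_id` order, making the output invariant to row order.

The composite `rule = "auto"` applies the percentile rule to the
reference period and top-k with the reference period's margin count to
the rest — the natural protocol when the first survey was range-wide
and later ones tracked the moving edge.

**Pooled periods.** A label like `"2012-14"` maps to the midpoint year
2013 by default (`period_year_map()`); the mapping is user-overridable
since the choice of regression year for a pooled survey is a modeling
decision, not a fact of the data.

**Periphery extraction** (`extract_periphery()`). One minimum enclosing
circle *per period* (a single global circle is available behind
`global_circle = TRUE`): the periphery tracks the moving edge, so a
fixed circle would mix interior and edge dynamics. The circle is
computed by Welzl's algorithm; because the minimum enclosing circle is
unique, results do not depend on point order.

## The candidate trend models

Five mean structures, each fit by exact maximum likelihood for the
Gaussian (identity link) and binomial (logit link) families:
constant, linear, quadratic, and two one-breakpoint forms built on the
hinge (t − ψ)₊ = max(0, t − ψ):

* **left-horizontal**: β₀ + γ(t − ψ)₊ — stasis, then expansion at rate
  γ from year ψ;
* **two-slope**: β₀ + β₁t + γ(t − ψ)₊ — two linear phases; the
  post-breakpoint slope is β₁ + γ, reported as `year_right`.

### Breakpoint estimation

With ψ fixed, each model is a linear (or generalized linear) model; ψ
itself is estimated by the iterative linearization classically used for
segmented regression. The design is augmented with
U = (t − ψ)₊ and V = −1[t > ψ]; after each weighted fit the working
estimate moves by ψ ← ψ + β̂ᵥ/γ̂ᵤ (a Newton-type step), with steps
larger than a quarter of the admissible range halved until acceptable,
and ψ clamped to (min t + ε, max t − ε) where ε is half the smallest
gap between distinct years. The iteration starts from the best of 10
interior-quantile candidates evaluated on the profile likelihood, and
stops when the update falls below 10⁻⁸ years or after 100 iterations.

Because the profile negative log-likelihood is only piecewise smooth in
ψ (it has kinks at the observed years) and the linearization can stall
between kinks, a converged solution is then *certified*: the profile is
minimized by bounded one-dimensional optimization within each
distinct-year interval (all intervals when there are few; otherwise the
interval bracketing the working estimate), and the best point wins.
The test suite verifies that the returned fit never loses to a
0.01-year profile grid around ψ̂ by more than 10⁻⁶ in negative
log-likelihood, for both families. A ψ̂ driven to the clamp boundary
raises an error naming the offending side rather than returning a
spurious interior estimate.

### Uncertainty

SE(ψ) is the delta-method ratio SE(β̂ᵥ)/|γ̂ᵤ| from the augmented model
at the solution — approximate when distinct years are few, and
undefined (reported `NA`) when ψ̂ lands exactly on an observed-year
kink, where the profile has no curvature to exploit.

Coefficient covariance is taken from the **V-augmented** working model,
not the conditional fit at fixed ψ̂: the extra breakpoint column
propagates ψ-uncertainty into the slope standard errors. In simulation
this matters a great deal — conditional-on-ψ̂ standard errors for the
post-breakpoint slope are roughly half the true sampling variability in
the study-like design, while the augmented ones track it. Even so,
Wald intervals in the *left-horizontal* form undercover in this design
(the zero-slope constraint couples ψ̂ and γ̂ strongly); the
unconstrained two-slope form attains close-to-nominal coverage, which
is why the recovery checks in the test suite assess slope coverage on
the two-slope fit and breakpoint recovery on the left-horizontal fit.
Gaussian intervals use t quantiles with n − np degrees of freedom;
binomial intervals use normal quantiles.

### Parameterization of year

All forms except the Gaussian quadratic are fitted on t = year −
min(year), which conditions the design and makes the intercept the
fitted level at the first survey year. The Gaussian quadratic is fitted
on raw calendar year by default — the conventional reporting scale for
distance-vs-year curvature — with `year_origin` available to override
either choice. Breakpoints are always reported on the calendar scale.
Likelihoods, AICc and weights are invariant to this choice.

### The pseudo-score breakpoint test

Under the no-breakpoint null, ψ is not identified, so a likelihood
ratio against the segmented alternative has no standard distribution.
The pseudo-score approach sidesteps this: average the hinge regressors
over K quantile-spaced candidate breakpoints (default K = 10),
add that single column to the null design, and test its coefficient —
an exact t test for the Gaussian family (so finite-sample type-I error
is exactly nominal), a Wald z for the binomial. The null is the linear
model, or the constant model when the alternative is left-horizontal.
A seeded parametric bootstrap (default 999 replicates) of the same
statistic under the fitted null is provided as the arbiter in settings
where the closed-form reference distribution is in doubt; the test
suite checks the two modes agree on strong-signal data and that the
Gaussian null rejection rate is calibrated.

## Model selection

AICc = 2·NLL + 2k + 2k(k+1)/(n − k − 1), with NLL the exact negative
log-likelihood at the optimum — for the Gaussian family the closed form
(n/2)(log 2π + log(RSS/n) + 1), constants included. The effective count
k is the mean-structure parameter count *including ψ* (constant 1,
linear 2, quadratic 3, left-horizontal 3, two-slope 4) plus one for the
Gaussian residual variance; the binomial family has no dispersion
parameter. Comparison tables report NLL (note: published tables in this
literature sometimes label this column "−2LL" although the numbers are
−LL; the AICc reconstruction disambiguates). Akaike weights are
normalized over *converged* fits only — silently including a
non-converged likelihood would corrupt the evidence ratios — and the
ΔAICc ≤ 2 "substantial support" flag is an annotation, not a decision
rule.

## The synthetic-data generator

The generator emulates the study conditions the models assume: five
survey periods (1985, 2003, pooled 2012–14 at 2013, 2019, 2021), six
margin observations per period (30 in all), and 126 periphery
presence–absence records split as evenly as possible across periods.

* **Margin distances**: hinge trajectory with breakpoint 2006, stasis
  level 162.5 km, post-breakpoint slope 5.48 km/yr, Gaussian noise
  σ = 17.6 km. σ is not a free invention: it is the residual SD implied
  by inverting the Gaussian NLL closed form at NLL = 128.68, n = 30
  (`implied_sigma()`; the inversion is unit-tested), i.e. the noise
  level consistent with the published fit quality of such a series.
* **Occupancy**: Bernoulli draws from a two-segment logit path exactly
  through occupancy 0.151 in 1985, 0.658 at the 2019 breakpoint, and
  0.289 in 2021 (`occupancy_params()` solves the segment slopes from
  these anchors). An optional second breakpoint (`psi2`,
  `slope_right2`) supports three-segment trajectories; the analysis
  models deliberately remain single-breakpoint, mirroring the intended
  mis-specification stress.
* **Spatial snapshots** (`simulate_spatial_survey()`): margin points
  planted in the northern half-plane at hinge-mean distance plus noise
  (margin decoys are never placed south of the center, since selection
  is northward-directional); the reference period gets a range-wide
  complement of interior occurrences over the full disc (110 by
  default) so that the 95th-percentile rule selects about six sites
  there and the occurrence centroid approximates the planted center;
  later periods get a thin periphery-restricted complement, plus
  occupancy-labelled periphery sites just inside the margin ring.

What the generator does *not* emulate: spatial autocorrelation of
detections along river networks, imperfect detection, survey-effort
drift between periods, and non-Gaussian distance noise. Passing
recovery tests therefore demonstrate correctness of the estimators
under the stated model, not robustness to those field realities.

## Numerical choices and degenerate inputs

* Segmented control defaults: tol 10⁻⁸ yr, max 100 iterations, 10-point
  profile init, step-halving factor 0.5 (`seg_control()`).
* Admissible breakpoints: (min t + ε, max t − ε), ε = half the smallest
  distinct-year gap; two-slope additionally needs 4 distinct years,
  left-horizontal 3.
* Binomial IRLS: deviance tolerance 10⁻¹⁰, max 100 iterations;
  separation is flagged (`converged = FALSE`) when any fitted linear
  predictor exceeds 15 in absolute value.
* Perfect fits (zero residual variance) are flagged `degenerate`; the
  pseudo-score test refuses them; rank-deficient designs (e.g. a linear
  fit to one distinct year) raise a rank error.
* Minimum enclosing circle: exact for 1–2 points; boundary tolerance
  10⁻⁹ km; collinear triples fall back to the widest diameter pair.
* All stochastic steps (grid draws, generators, bootstrap) take a seed
  and restore the caller's RNG state; outputs record the seed.

## Problem sizes used in validation

The bundled checks run at the scale of the study design they emulate:
recovery experiments use 500 replicates of the 30-observation margin
design, test calibration uses 500 null replicates, the geometric oracle
comparison uses 200 random instances of up to 25 points against an
O(n⁴) brute force, and fit-vs-profile certification uses 50 seeded
datasets per family. These sizes give Monte-Carlo standard errors
comfortably inside the tolerance bands being checked.

## Known limitations

* Coordinates must already be in a planar metric projection; distances
  are Euclidean km. Geographic coordinates must be projected upstream.
* One breakpoint per model. Occupancy trajectories with two real bends
  will load weight on the two-slope form with the dominant bend.
* The delta-method SE(ψ) is approximate with few distinct survey years
  and unavailable exactly at data-year kinks.
* Naive occupancy: detection probability is assumed comparable across
  periods; no occupancy-model (imperfect-detection) layer is fitted.
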