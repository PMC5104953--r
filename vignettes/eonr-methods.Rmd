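---
title: "Methods: yield response fitting, economic optimum N, and the synthetic trial generator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: yield response fitting, economic optimum N, and the synthetic trial generator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nresponse)
```

## The problem

Corn growers must choose a nitrogen fertilizer rate before the season's
weather is known. The standard agronomic answer is the *economic optimum N
rate* (EONR): the rate at which the last kilogram of fertilizer just pays for
itself in grain. Because grain and fertilizer prices enter only through their
ratio, the break-even condition is a slope condition on the yield response
curve: at the optimum, marginal yield per kg N equals the price ratio
(kg grain per kg N; 5.6 by default, the long-run historical ratio).

This package implements that analysis end to end for multi-year, replicated
N-rate trials in continuous-corn (CC) and soybean-corn (SC) rotations:
response-curve fitting, optimum derivation by two techniques, site-mean
pooling, simulated-versus-observed agreement scoring, and regression analysis
of what drives year-to-year EONR variability. A seeded synthetic trial
generator with closed-form true optima makes every step testable by parameter
recovery.

## Yield response models

Two response forms are fitted per year and rotation, yield `y` (kg/ha)
against fertilizer rate `x` (kg N/ha):

* **Quadratic**: `y = a + b x + c x^2`, by ordinary least squares.
* **Quadratic-plus-plateau**: the same parabola up to a join point `x0`,
  constant beyond it.

For the plateau form we constrain the join point to the parabola's vertex,
`x0 = -b / (2c)`, which makes the curve continuously differentiable. The
unconstrained variant (a free `x0` with a kink) exists in the literature, but
a derivative-based economic optimum presupposes a well-defined slope, and the
smooth form is the common convention in nonlinear trial analysis; we
implement only the smooth variant.

With `x0` fixed, the plateau model is *linear* in its remaining parameters
(regress `y` on the basis `z(x) = x^2 - 2 x0 x` below the join, `-x0^2`
above). Fitting therefore profiles `x0` over a dense deterministic grid
spanning `[min(x), 1.5 * max(x)]` (300 points by default), solving a
closed-form two-parameter regression at each candidate, then refines the best
bracket with `stats::optimize()`. No random restarts: the fit is exactly
reproducible and seed-independent. A fit is flagged `converged = FALSE` —
reported, never raised — when the best profile point has non-negative
curvature or sits at the profile boundary (e.g. monotone data whose plateau
lies beyond anything identifiable).

**Model selection** mirrors standard practice for these trials: candidates
must converge and be significant at `alpha` (default 0.05, overall F-test
against the intercept-only model — the test is our choice; significance
thresholds in trial reports rarely name one), and the survivor with the
smaller residual sum of squares wins. Exact ties go to the plateau form, the
biologically bounded response. If nothing survives, the group is
*non-responsive* and its optimum is left undefined — undefined years
propagate as missing, never as zero, so they cannot drag down a site mean.

The R² reported for the plateau fit is `1 - SS_res / SS_tot`, the plain
nonlinear-regression convention.

**Fit level.** Replicate-level observations are the default (about 20 points
per group with 5 rates and 4 replicates); `level = "mean"` fits treatment
means instead. On noiseless data the two are identical (a property the test
suite asserts); on real data replicate-level fitting weights rates by their
replication and yields honest residual degrees of freedom.

## Economic optimum: two techniques

**Regression EONR.** Solve `b + 2 c N = r` for the price ratio `r`:
`N* = (r - b) / (2c)`, capped at the join point for plateau fits (beyond
`x0` the slope is zero, below any positive ratio). The yield at the optimum
(YEONR) is the fitted value at `N*`. Estimates are clamped to `[0,
max_rate]` — by default the largest tested rate — with an explicit boundary
flag (`interior`, `at_zero`, `at_max`, `undefined`) rather than
extrapolating: observed optima in long-term trials do hit the top tested
rate, and a censored estimate labelled as such is more honest than an
extrapolated one.

**Return-to-N (RTN) scan.** Given yields on a fine fertilizer grid (default
every 5 kg from 0 to 350), marginal net return between consecutive rates is
`ΔR_i = (Y_{i+1} - Y_i) - r (N_{i+1} - N_i)`; the optimum is where it first
reaches zero. We compute both that first zero-crossing and the grid maximizer
of cumulative return `Y(N) - r N`. For concave curves they coincide (and sit
within one grid step of the analytic optimum — asserted over hundreds of
random concave responses in the tests); on noisy non-concave curves they can
disagree, in which case the cumulative maximizer is returned and the signed
discrepancy is attached to the result, because "first crossing" on a noisy
curve is an artifact of noise ordering while the cumulative maximizer is the
actual profit argmax on the grid.

**Site means, two ways.** `across_years` averages the defined yearly
estimates and reports their SD; `pooled` averages yields per rate across
years first and runs the whole chain once on the mean response (the approach
regional N recommendations use). The two agree exactly on identical
noiseless years and differ on real data — the package computes both and
`method_difference()` reports exact signed differences between any two
defined estimates (differences of independently rounded published means can
differ by 1 from the printed difference; we report the exact subtraction).

## Agreement statistics

RMSE and relative RMSE (`100 * RMSE / mean(observed)`) quantify
simulated-versus-observed agreement, with the conventional crop-modelling
bands: RRMSE ≤ 15% good, strictly between 15 and 30% moderate, ≥ 30% poor
(both boundary values resolve by the wording of the bands: 15 is good, 30 is
poor). `evaluation_report()` pairs model output against observed *treatment
means* on (year, rotation, N rate) — simulators emit one value per
treatment — and reports per-rate rows plus a pooled "Mean" row per rotation
computed over all of that rotation's pairs. The Mean row is *not* the
average of the per-rate statistics (RRMSE is not additive across groups);
the tests assert the distinction. The CV uses the sample (n−1) SD.

## The synthetic trial generator

The generator is a minimal statistical stand-in for a process-based
crop-soil simulator: it reproduces the *structure* the analysis assumes —
not any particular site's yields — while keeping every piece analytically
checkable.

Per year: weather (annual precipitation ~ N(900, 180) mm clipped to
[550, 1300]; spring, Apr 1–Jun 30 window ~ N(400, 90) clipped to
[150, min(700, annual)]; July silking window ~ N(110, 45) clipped to
[0, annual − spring]) and a multiplicative year factor ~ N(1, 0.13)
truncated at 0.4 (guards against negative yields; resampled, so effectively
exact at this CV). Then per rotation:

* **Soil N supply** `S = s0 * f_rot * max(0.5, 1 + s_p (P_spring - 400))`
  plus atmospheric deposition `0.01 * P_annual` kg N/ha (linear, so daily
  sums equal the annual product; ~7 kg over a 700 mm season). Defaults
  `s0 = 80` kg N/ha for CC and `f_rot = 1.5` for SC — the rotation credit
  that makes SC supply 50% higher and its optima correspondingly lower.
* **Fertilizer loss fraction**
  `L = min(0.8, 0.08 * exp(0.004 (P_spring - 400)))` — the exponential
  denitrification-plus-leaching response to wet springs.
* **Expected yield**: available N `A = S + (1 - L) N`; a smooth
  quadratic-plateau in `A` (`y0 = 2000`, `b = 85`, `c = -0.16`; vertex
  `A0 ≈ 266` kg N/ha, plateau ≈ 13.3 Mg/ha) scaled by the year factor.
* **Replicates**: expected yield times `(1 + N(0, 0.08))`, four per rate at
  the five classic rates 0/67/134/201/268 kg N/ha. SC plots also carry
  soybean rows ~ N(3400, 660) kg/ha, drawn independently of the N applied
  to the prior corn — the no-carryover null the drivers module checks.

Because `A(N)` is affine, the true response in *applied* N is again a smooth
quadratic-plateau, so the fitting chain can recover the truth exactly on
noiseless means (asserted to within 2 kg N across a 50-scenario sweep). The
true optimum has the closed form
`A* = (r / ((1-L) yf) - b) / (2c)`, `N* = (A* - S) / (1 - L)`, cross-checked
internally against dense numeric profit maximization on every call.

Defaults put true optima near 205 (CC) and 155 (SC) kg N/ha at reference
precipitation, with yearly yield CVs around 13%, EONR SDs of 20–50 kg N/ha
and mean yields in the 8–13 Mg/ha range — the magnitudes long-term Midwest
trials report. What the generator does **not** emulate: water-table and soil
water dynamics, organic-matter pools, residue effects, within-season N
timing, spatial structure, or any real site's year sequence. Passing
recovery tests therefore demonstrates that the estimation chain is correct
and well-calibrated *for data of this structure*; it says nothing about how
well a quadratic-plateau describes any particular field.

The rotation design is simplified: synthetic SC carries corn (and soybean)
rows every year so that ground truth exists for every year × rotation,
whereas a real SC rotation alternates phases. All draws flow from one seeded
stream (`seed` argument), and global RNG state is always restored.

## Drivers of year-to-year variability

`window_sum()` sums daily precipitation over month-day windows (endpoints
inclusive; Apr 1–Jun 30 is the canonical spring window — 91 days in any
year). `screen_windows()` regresses yearly EONR on each candidate window's
sum and ranks by R², flagging significance; undefined years drop pairwise.
`simulate_daily_precip()` disaggregates the generator's seasonal sums onto
calendar days (Exponential(1) weights per window, normalized), so window
screens reproduce the seasonal sums exactly. `carryover_check()` regresses
soybean yield on prior-corn N; on generator output its rejection rate is the
nominal type-I error, and a planted slope is recovered. The multi-factor
regression is deliberately descriptive only — no selection decisions are
made from it.

A note on statistical power, computed by the acceptance suite rather than
assumed: the mechanism puts a ~0.1 kg N per mm slope into the *true* optima,
and over 16-year runs that slope is positive essentially always. Year-level
EONR *estimates*, however, carry ~20–30 kg N of error at the default noise
(median absolute recovery error is bounded at 25 kg N in the tests), so a
single 16-year trial often cannot resolve the slope's sign from estimates
alone — which is exactly why the mechanism tests run on the generator's
ground truth, with the estimated-slope average across seeds checked for
sign. The same power problem faces real trials, where the observed
EONR-versus-spring-precipitation relationship is significant but weak.

## Numerical choices and edge cases

* Canonical units everywhere internally: kg/ha, kg N/ha; `mg_ha` I/O is
  converted at the boundary, and unit choice provably cannot change EONR or
  RRMSE.
* Plateau profile: 300-point grid + `optimize()` refinement to 1e-6;
  the suite checks the profile SS against an exhaustive 0.1-kg grid search.
* Degenerate inputs: constant yields give a null, non-significant fit;
  fewer than 3 distinct rates or 4 points raise an "unfittable" error;
  convex fitted curvature yields an `undefined` optimum, not an error;
  a zero-variance predictor flags the regression as degenerate; a constant
  response returns an exact zero slope with R² = 0.
* RTN grids must be strictly increasing and uniformly spaced; gaps are an
  input error, not silently tolerated.
* Problem sizes in the test and acceptance suites (1000 random responses for
  the analytic oracle, 100 simulated years for noisy recovery, 20 + 50 seeds
  for the mechanism checks) were chosen as the smallest batches whose
  Monte-Carlo noise is well below the tolerances they assert.

## Known limitations

* Only the two response forms above are fitted; linear-plateau,
  square-root and Mitscherlich forms are out of scope.
* The price ratio is fixed across years; no price-scenario sweeps.
* The generator's loss/supply mechanism is phenomenological; its parameters
  are not calibrated to any site, and exact reproduction of any published
  trial's yields is explicitly not a goal.
* Pooled "Mean" agreement rows use pooled pairs; a replication-weighted
  average is the documented alternative convention, not implemented.
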