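---
title: "Modeling developmental kinetics under dietary sugar stress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling developmental kinetics under dietary sugar stress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(devkin)
```

## The data and the question

The assay behind this package seeds a fixed number of synchronized embryos
(50 per vial, 5 replicate vials) on media spanning a sucrose gradient
(11 concentrations, 0–1.5 M in 0.15 M steps) and records the cumulative
number of new pupae every 8 hours. Time is measured in hours from the
midpoint of the 2 h embryo-collection window, so the whole curve lives on
one common developmental clock. Two questions drive the analysis: *when*
does the population develop (timing), and *how tightly clustered* are the
individual developmental times (synchrony) — and how both change with the
diet.

## Primary models

Replicate vials at one concentration are averaged pointwise into a single
treatment curve (`aggregate_replicates()`), then divided by the final count
so the response is a proportion ending at exactly 1
(`normalize_curve()`). Averaging raw counts before normalizing is the
adopted order; for vials seeded with equal embryo numbers the reverse order
gives the same curve, so nothing hinges on it there, and viability is
always computed per vial before averaging. When replicate vials were read
on different grids, the union of observation times is used and each vial's
last observed count is carried forward — cumulative counts are step
functions, so this adds no interpolation assumption and preserves
monotonicity.

Three sigmoids are fitted to the normalized curve:

* **Gompertz** `y(t) = exp(-exp(s_dvp · e · (λ - t) + 1))`. The lower
  asymptote is fixed at 0 (observation starts at embryo collection, before
  any pupariation) and the upper at 1 (normalized data); the general
  four-parameter form exists in `gompertz_predict()` for completeness but
  the pipeline never frees those asymptotes. Under this parameterization
  `s_dvp` (1/h) is *exactly* the maximum slope of the curve, attained at
  `y = 1/e` — a property the test suite checks numerically — and the lag
  `λ` (h) shifts the curve along the time axis. The mean time follows in
  closed form, `t_mid = λ + (1 - ln ln 2)/(e · s_dvp)`, which the suite
  verifies against a bisection root-find to 1e-9 h.
* **Log-dose logistic**
  `y(t) = 1/(1 + 10^(-s_dvp (log10 t - log10 t_mid)))`, the pharmacological
  dose–response curve with log10 time as the dose axis. Its `s_dvp` is a
  dimensionless log-time steepness — numerically in the tens for these
  data — and is not comparable unit-for-unit with the Gompertz rate. The
  model is undefined at `t = 0`; `fit_dose_response()` refuses such
  curves, and the pipeline drops the structural `t = 0, y = 0` point
  before fitting this model only.
* **Logit linearization** `ln(y/(1-y))` regressed on time by OLS;
  `s_dvp` (1/h) is the slope, `t_mid` the x-intercept. Points with
  `y ∈ {0, 1}` have no finite logit and are dropped (their count is kept
  and reported); no continuity correction is applied, because a correction
  would introduce a tuning constant the data cannot inform. Fit
  diagnostics for this model are computed after back-transforming to the
  probability scale: logit-scale residuals are centered near zero, which
  makes a mean-normalized RMSE meaningless.

Nonlinear fits use bounded Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`, `ftol = 1e-10`) with deterministic initialization:
`λ` starts at the last time the curve is still 0, the rate at the maximum
finite-difference slope. Bounds are `s_dvp > 1e-6` and `λ ∈ [0, max t]`.
There are no random restarts, so a given curve always yields the same fit.

Diagnostics per fit: `SSE`, `R² = 1 - SSE/SStot`, and
`nRMSE = 100 · sqrt(SSE/n) / mean(y_obs)` — RMSE as a percentage of the
observed mean, the convention that puts normalized-curve and
reaction-norm fits on comparable footing.

## Secondary models: reaction norms and the stress breakpoint

The fitted `t_mid(E)` and `s_dvp(E)` are treated as phenotypic reaction
norms over sucrose concentration `E`. Two candidates are compared:

* linear, `y = aE + b` (k = 2), and
* bilinear, two free lines `y = a1·E + b1` for `E ≤ x_c` and
  `y = a2·E + b2` for `E > x_c`, with the breakpoint defined by the
  intersection `x_c = (b2 - b1)/(a1 - a2)` (k = 4; `x_c` is derived, not a
  free parameter).

`fit_bilinear()` is deliberately not a gradient-based optimizer: with 11
grid points there are at most 8 ways to split the sorted concentrations
into two blocks of ≥ 2, so the fitter enumerates them all, fits OLS per
block, and keeps the candidate with the smallest total piecewise SSE. A
candidate only counts when its intersection is consistent with the
partition it was fitted on: `x_c` must fall in the half-open bracket
`[x_m, x_{m+1})` between the blocks (closed on the left because the left
segment owns `x ≤ x_c`; a 1e-9-of-range tolerance absorbs floating-point
error — without the closed edge, data whose kink sits exactly on a grid
point would be rejected by their own best split). SSE ties break toward
the smaller split index, so the fit is fully deterministic. If no split is
admissible, the minimum-SSE split is returned with `x_c` clamped to its
bracket midpoint and flagged `fallback = TRUE` rather than failing — a
flagged estimate is more useful downstream (and to the bootstrap) than an
error. The test suite proves the fitter identical to an independently
written brute-force enumeration on hundreds of random datasets.

Model choice uses the SSE form of Akaike's criterion,
`AIC = n · ln(SSE/n) + 2k`, with no small-sample correction and no
additive constants — the variant appropriate when both models are fitted
to the same data by least squares and only differences matter.
`ΔAIC = AIC_linear - AIC_bilinear > 2` is read as support for a real
breakpoint. Because the bilinear family also spends its extra parameters
on an adaptive split, its false-selection rate under a straight-line truth
is materially higher than the textbook "2 points of AIC" intuition
suggests: in the suite's seeded simulation at the reference residual
scale, roughly a quarter of pure-line datasets still clear ΔAIC > 2. The
threshold is kept because it is the conventional reporting line, but the
bootstrap interval — not ΔAIC alone — should carry the inferential weight.

### Breakpoint uncertainty

`residual_bootstrap_bilinear()` resamples the pooled residuals of the
piecewise fit with replacement, adds them back to the fitted values,
repeats the full split-enumeration fit, and reports percentile 2.5/97.5
bounds for `x_c` and the four line coefficients. Residuals are pooled
across the two segments (segment-wise resampling would leave as few as
2–4 residuals per segment). Refits that land in the clamped-midpoint
fallback keep their `x_c` and are counted (`n_fallback`): discarding them
would systematically narrow the intervals. Only outright refit errors are
dropped, and more than 20% of them aborts the run. Every resample draws
from its own counter-derived RNG stream
(`seed · 1000003 + b · 7919 mod 2³¹-1`), so results are bit-reproducible,
independent of iteration order, and distinct root seeds share no draws.

Percentile intervals were chosen over BCa or basic intervals as the
simplest procedure consistent with plain residual resampling. Their known
cost is mild undercoverage for irregular estimands like breakpoints: in
the package's own validation (200 synthetic reaction norms at the
reference noise scale, and 100 full simulate-fit-bootstrap replicates)
the nominal 95% interval covers the true breakpoint in the high-80s to
~90 percent of replicates, with misses dominated by intervals sitting
slightly below the truth — the split-enumeration point estimate drifts a
little low when estimation noise rounds off the kink. Users who need
strictly calibrated intervals should widen the level or average over
replicate experiments.

## Viability statistics

Per-vial viability (final count / embryos seeded) is grouped by
concentration and analyzed classically: one-way ANOVA with
`η² = SS_between/SS_total`, Tukey HSD pairwise comparisons, and a compact
letter display built greedily from the graph of non-significant pairs
(presentation only — the adjusted p-values carry the inference).
Homoscedasticity uses Levene's original mean-centered form (ANOVA on
absolute deviations from group means), and residual shape is summarized by
the adjusted Fisher–Pearson skewness and excess kurtosis — the spreadsheet
SKEW/KURT convention, matching how such assays are usually processed.
Viability fractions enter untransformed; with five replicates per group an
arcsine or logit transform changes little and complicates interpretation.
`α = 0.05` throughout.

## The synthetic-data generator

`build_truth()` + `generate_experiment()` simulate the full assay with
known ground truth, which is what makes end-to-end validation possible.
The generative model:

* survivors per vial ~ Binomial(`n_embryos`, viability(E));
* each survivor's pupariation time is drawn from the Gompertz curve read
  as a CDF, by inverse transform:
  `t(u) = λ + (1 - ln(-ln u))/(e · s_dvp)`, `u ~ U(0,1)` — so the
  empirical cumulative curve converges to the model being fitted (the
  suite checks the Kolmogorov–Smirnov distance at n = 1e5);
* counts are censored onto the 8 h grid from 0 h to 24 h past the vial's
  last event, so every curve reaches its plateau;
* per-vial seeds derive from the root seed by concentration and vial
  index, making any subset reproducible in isolation.

Default truth values emulate the reference experiment: the synchrony norm
uses the published point estimates (intercept 0.0427, pre-break slope
−0.0466 per mol/L, post-break slope −0.0053, breakpoint 0.581 M, upper
intercept by continuity); the timing norm is the exact bilinear fit of the
reference Gompertz `t_mid` row (117.5 h + 40.07 h/M below 0.524 M,
slope 153.9 h/M above, continuous at the break); viability declines
linearly from 0.85 at 0 M to 0.55 at 1.5 M, a realistic survival gradient
for this design. `λ(E)` is back-computed from the timing and synchrony
norms through the closed form, so simulated curves have exactly the
requested `t_mid(E)`.

What the generator does **not** emulate: between-vial random effects
(individual times are i.i.d. given the concentration), time-varying
mortality, larval crowding, or any separation between pupariation and
eclosion beyond a constant offset. Passing recovery tests on these data
therefore demonstrates correctness of the estimation machinery under the
model's own assumptions, not robustness to biological structure the model
omits.

`downsample_schedule()` thins a vial to 1, 2 or 3 observations per day,
with time 0 pinned to 9 a.m. (so "9 a.m./5 p.m." is offsets {0, 8} h and
"9 a.m." is {0}). Thinning removes observation times only — retained
counts are untouched — which is exactly what a lower-frequency reading of
the same vials would have produced.
`sampling_frequency_experiment()` rebuilds the whole primary + secondary
pipeline per schedule; on low-stress-only designs a once-daily schedule
leaves too few informative points and the failure surfaces as explicit
warnings or errors, never as silently degraded numbers.

## Problem sizes used in validation

The shipped test suite validates the oracle identities on parameter grids,
the bilinear fitter against brute force on 200 random datasets, sampler
distribution at n = 1e5, bootstrap behavior at 1000 resamples, bootstrap
coverage on 200 synthetic reaction norms, and end-to-end breakpoint
recovery on 100 simulated experiments (55 vials each, bootstrap at 400
resamples) — sizes chosen to make Monte-Carlo error small relative to the
assertions while keeping the default check run comfortably interactive.

## Known limitations

* The bilinear model is two free lines, not a continuity-constrained
  segmented regression; with noisy data the fitted segments can disagree
  slightly at the break. This is intentional — the breakpoint is defined
  as the intersection of the two fitted phases.
* Percentile bootstrap intervals for the breakpoint undercover mildly
  (see above).
* The logit model's `s_dvp` is on a different scale from the Gompertz
  maximum rate (steeper by roughly the logistic-vs-Gompertz shape factor);
  compare synchrony across diets within one model, not across models.
* `nRMSE` divides by the mean observed value; for responses centered near
  zero (not the case for cumulative proportions) it would be unstable.
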