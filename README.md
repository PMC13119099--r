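# devkin

Quantitative modeling of *Drosophila melanogaster* developmental kinetics
under dietary stress.

Feeding assays that track cumulative pupariation (or adult eclosion) in
replicate vials usually get reported as descriptive curves. `devkin` turns
those counts into a small set of interpretable phenotypes and models how
they respond to the diet:

1. **Primary models** fit the normalized cumulative curve
   `y(t) = y_obs / y_max` at one fixed diet and extract
   - `t_mid` — mean developmental time, where the curve crosses 0.5, and
   - `s_dvp` — developmental synchrony, the steepness of the transition
     (lower values = more spread-out individual development).

   Three sigmoids are implemented:
   - **Gompertz**: `y(t) = exp(-exp(s_dvp · e · (λ - t) + 1))`, with lag
     `λ` and the closed form
     `t_mid = λ + (1 - ln ln 2) / (e · s_dvp)`; `s_dvp` is exactly the
     curve's maximum slope (1/h), attained at `y = 1/e`.
   - **Log-dose logistic** (dose–response with log10 time in the role of
     log dose): `y(t) = 1 / (1 + 10^(-s_dvp (log10 t - log10 t_mid)))`.
   - **Logit linearization**: `ln(y / (1 - y))` regressed on time;
     `s_dvp` is the slope and `t_mid` the x-intercept.

2. **Secondary models** treat `t_mid(E)` and `s_dvp(E)` as reaction norms
   of the sucrose concentration `E` (mol/L). A straight line `y = a·E + b`
   competes against a **bilinear** model — two free lines
   `y = a1·E + b1` (below) and `y = a2·E + b2` (above) meeting at the
   breakpoint `x_c = (b2 - b1) / (a1 - a2)` — fitted by deterministic
   exhaustive split enumeration. Model choice uses the SSE-based criterion
   `AIC = n · ln(SSE/n) + 2k` (k = 2 linear, 4 bilinear); breakpoint
   uncertainty comes from a residual bootstrap. The breakpoint marks the
   concentration where developmental timing and synchrony stop responding
   to further sugar — an operational definition of a high-sugar diet.

The package also ships replicate-level viability statistics (one-way ANOVA
with η², Tukey HSD with compact letters, mean-centered Levene test,
residual moments), a synthetic vial-count generator with known ground-truth
reaction norms (Gompertz event-time sampling by inverse transform, binomial
survival, grid-censored observation), and observation-schedule thinning for
sampling-frequency studies.

## Worked example

The packaged reference tables (`reference_parameter_table()`) hold `t_mid`
and `s_dvp` for all three primary models across 11 sucrose concentrations
(0–1.5 M in 0.15 M steps). Fitting the bilinear reaction norm to the
Gompertz synchrony row:

```r
library(devkin)
tab  <- reference_parameter_table("s_dvp")
gomp <- tab[tab$model == "gompertz", ]
fit  <- fit_bilinear(gomp$concentration_M, gomp$s_dvp, parameter = "s_dvp")
fit
#> <secondary_fit:bilinear> s_dvp  x_c = 0.5927 M
#>   left:  y = -0.04467 x + 0.0428
#>   right: y = -0.005714 x + 0.01971
#>   n=11 k=4  SSE=1.316e-05  AIC=-142.00  R2=0.9889  nRMSE=5.30%
```

Synchrony falls steeply (−0.045 per mol/L) up to ≈0.59 M sucrose and is
nearly flat beyond — development is maximally de-synchronized once the diet
crosses the stress threshold. The bilinear model is strongly preferred over
a single line (`compare_linear_bilinear()` gives ΔAIC = 27.3), and the
breakpoint is well identified:

```r
residual_bootstrap_bilinear(gomp$concentration_M, gomp$s_dvp,
                            n_boot = 1000, seed = 1)
#> <bilinear_bootstrap> 1000 resamples, seed 1, 95% percentile intervals
#>   115 refits used the clamped-midpoint fallback
#>   statistic     point     lower     upper
#> 1       x_c  0.592700  0.506600  0.682000
#> 2        a1 -0.044670 -0.052030 -0.038280
#> 3        b1  0.042800  0.040520  0.044440
#> 4        a2 -0.005714 -0.008956 -0.001153
#> 5        b2  0.019710  0.014020  0.022780
```

For raw vial counts, the same analysis runs end to end from a long-format
CSV (`vial_id, concentration_M, n_embryos, time_h, cum_pupae`):

```r
vials <- read_counts_csv("counts.csv")        # or generate_experiment()
out   <- run_pipeline(vials, pipeline_config(), out_dir = "results")
```

which writes the primary parameter table, the secondary reaction-norm JSON
(with bootstrap intervals and provenance), the sampling-frequency
comparison, and the viability statistics.

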