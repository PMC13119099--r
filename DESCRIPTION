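Package: devkin
Title: Primary and Secondary Modeling of Drosophila Developmental Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits sigmoid primary models (Gompertz, log-dose logistic, logit
    linearization) to normalized cumulative pupariation or eclosion curves of
    Drosophila melanogaster to extract developmental timing (t_mid) and
    synchrony (s_dvp) parameters, and models these parameters as reaction
    norms of dietary sucrose concentration with linear and bilinear
    (breakpoint) secondary fits, SSE-based AIC model selection, and residual
    bootstrap confidence intervals. Includes replicate-level viability
    statistics (one-way ANOVA with effect size, Tukey HSD letters, Levene's
    test), a synthetic vial-count generator with Gompertz event-time sampling
    and bilinear ground-truth reaction norms, and observation-schedule
    downsampling utilities for sampling-frequency studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    car,
    e1071,
    withr,
    yaml
Config/testthat/edition: 3
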