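# Independent oracles and small fixture builders used across the suite.

# Brute-force bilinear fit: direct enumeration of every split with lm() per
# block, admissibility filter applied afterwards, global SSE minimum among
# admissible candidates. Written independently of the package's fitter.
brute_force_bilinear <- function(x, y) {
  o <- order(x)
  x <- x[o]
  y <- y[o]
  n <- length(x)
  cands <- list()
  for (m in 2:(n - 2)) {
    dl <- data.frame(x = x[1:m], y = y[1:m])
    dr <- data.frame(x = x[(m + 1):n], y = y[(m + 1):n])
    cl <- coef(lm(y ~ x, data = dl))
    cr <- coef(lm(y ~ x, data = dr))
    if (cl[["x"]] == cr[["x"]]) next
    xc <- (cr[["(Intercept)"]] - cl[["(Intercept)"]]) / (cl[["x"]] - cr[["x"]])
    # left segment covers x <= xc, so admissibility is left-closed
    if (!(xc >= x[m] - 1e-9 * (x[n] - x[1]) && xc < x[m + 1])) next
    pred <- ifelse(x <= xc,
                   cl[["x"]] * x + cl[["(Intercept)"]],
                   cr[["x"]] * x + cr[["(Intercept)"]])
    cands[[length(cands) + 1L]] <- list(
      m = m, xc = xc, sse = sum((y - pred)^2),
      a1 = cl[["x"]], b1 = cl[["(Intercept)"]],
      a2 = cr[["x"]], b2 = cr[["(Intercept)"]])
  }
  if (!length(cands)) return(NULL)
  sses <- vapply(cands, function(c) c$sse, numeric(1))
  cands[[which.min(sses)]]
}

# Plain bisection root-find of gompertz_predict(t) = target.
bisect_gompertz <- function(s_dvp, lambda, target = 0.5, tol = 1e-12) {
  lo <- lambda
  hi <- lambda + 10 / s_dvp
  stopifnot(gompertz_predict(lo, s_dvp, lambda) < target,
            gompertz_predict(hi, s_dvp, lambda) > target)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (gompertz_predict(mid, s_dvp, lambda) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Kolmogorov-Smirnov distance between a sample and a CDF function.
ks_distance <- function(sample, cdf) {
  s <- sort(sample)
  n <- length(s)
  fs <- cdf(s)
  max(abs(seq_len(n) / n - fs), abs((seq_len(n) - 1) / n - fs))
}

# A clean normalized curve sampled from the Gompertz model on an 8 h grid.
make_gompertz_curve <- function(s_dvp = 0.03, lambda = 120,
                                concentration = 0, spacing = 8) {
  t_end <- gompertz_tmid(s_dvp, lambda) + 4 / s_dvp
  times <- seq(spacing, by = spacing,
               length.out = ceiling(t_end / spacing))
  y <- gompertz_predict(times, s_dvp, lambda)
  y <- y / y[length(y)]
  normalized_curve(concentration, times, pmin(y, 1))
}

# Reference reaction-norm rows (the packaged fixtures, inlined for tests
# that should not depend on file IO).
ref_conc <- seq(0, 1.5, by = 0.15)
ref_sdvp_gompertz <- c(0.043, 0.036, 0.029, 0.023, 0.016, 0.016, 0.015,
                       0.014, 0.010, 0.014, 0.011)
ref_tmid_gompertz <- c(121.7, 119.8, 124.4, 140.2, 153.3, 159.6, 199.8,
                       215.7, 260.7, 275.0, 271.5)

write_toy_counts_csv <- function(path, rows) {
  write.csv(rows, path, row.names = FALSE)
  path
}
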