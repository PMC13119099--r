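test_that("gompertz_predict matches its closed-form landmarks", {
  # at t = lambda the inner exponent is exactly 1
  expect_equal(gompertz_predict(110, 0.043, 110), exp(-exp(1)))
  expect_equal(gompertz_predict(1e6, 0.043, 110), 1)
  expect_equal(gompertz_predict(-1e6, 0.043, 110), 0)
  # half-response at the reference 0 M parameters
  expect_equal(gompertz_predict(121.69, 0.043, 110), 0.5, tolerance = 1e-3)
  expect_error(gompertz_predict(100, -0.01, 110), "s_dvp")
})

test_that("gompertz_tmid agrees with a bisection oracle across a grid", {
  for (s in c(0.005, 0.016, 0.043, 0.2, 1)) {
    for (l in c(0, 50, 110, 240)) {
      expect_lt(abs(gompertz_tmid(s, l) - bisect_gompertz(s, l)), 1e-9)
    }
  }
  # reference values: 0 M and 0.6 M entries of the published tables
  expect_equal(gompertz_tmid(0.043, 110), 121.69, tolerance = 1e-2)
  l6 <- gompertz_lambda(0.016, 153.3)
  expect_lt(abs(gompertz_tmid(0.016, l6) - 153.3), 1e-6)
  # infinitely synchronous development: t_mid collapses onto the lag
  expect_equal(gompertz_tmid(1e9, 70), 70, tolerance = 1e-6)
  expect_error(gompertz_tmid(0, 100), "s_dvp")
})

test_that("the maximum slope of the Gompertz curve equals s_dvp", {
  for (s in c(0.01, 0.043, 0.3)) {
    lambda <- 100
    t_star <- lambda + 1 / (exp(1) * s)   # where y = 1/e
    grid <- seq(t_star - 2 / s, t_star + 2 / s, length.out = 4001)
    h <- 1e-4 / s
    slope <- (gompertz_predict(grid + h, s, lambda) -
                gompertz_predict(grid - h, s, lambda)) / (2 * h)
    expect_lt(abs(max(slope) - s) / s, 1e-4)
    # and the maximum is attained at y = 1/e
    expect_equal(gompertz_predict(grid[which.max(slope)], s, lambda),
                 exp(-1), tolerance = 1e-3)
  }
})

test_that("fit_gompertz recovers exact-model and simulated parameters", {
  curve <- make_gompertz_curve(s_dvp = 0.03, lambda = 120)
  fit <- fit_gompertz(curve)
  expect_lt(abs(fit$s_dvp - 0.03) / 0.03, 1e-3)
  expect_lt(abs(fit$lambda - 120) / 120, 1e-3)
  expect_gt(fit$r2, 0.9999)
  expect_gt(fit$t_mid, fit$lambda)

  # simulated vials at the 0 M truth (s_dvp = 0.043, lambda ~ 110)
  truth <- build_truth(seed = 5L)
  vials <- generate_experiment(truth)$vials
  norm <- normalize_curve(aggregate_replicates(vials, 0))
  fit0 <- fit_gompertz(norm)
  expect_lt(abs(fit0$s_dvp - truth$s_dvp[1]) / truth$s_dvp[1], 0.15)
  expect_lt(abs(fit0$t_mid - truth$t_mid[1]), 2)
})

test_that("fit_gompertz rejects degenerate curves", {
  flat <- normalized_curve(1.5, seq(8, 48, by = 8), c(0, 0, 0, 1, 1, 1))
  expect_error(fit_gompertz(flat), "degenerate")
  expect_error(fit_gompertz(normalized_curve(0, c(8, 16, 24), c(0, 0.5, 1))),
               "at least 4 points")
})

test_that("dose_response_predict matches closed-form landmarks", {
  expect_equal(dose_response_predict(122.2, 20.98, 122.2), 0.5)
  expect_equal(dose_response_predict(135, 20.98, 122.2), 0.890,
               tolerance = 1e-3)
  # below the midpoint the response is below one half for any steepness
  for (s in c(0.5, 5, 50))
    expect_lt(dose_response_predict(121, s, 122.2), 0.5)
  expect_error(dose_response_predict(0, 20, 122), "t > 0")
  expect_error(dose_response_predict(-5, 20, 122), "t > 0")
})

test_that("fit_dose_response recovers exact-model parameters", {
  times <- seq(96, 280, by = 8)
  y <- dose_response_predict(times, 15, 150)
  y <- y / y[length(y)]
  curve <- normalized_curve(0, times, y)
  fit <- fit_dose_response(curve)
  expect_lt(abs(fit$s_dvp - 15) / 15, 1e-2)
  expect_lt(abs(fit$t_mid - 150) / 150, 1e-3)

  withzero <- normalized_curve(0, c(0, 104, 112, 120), c(0, 0.2, 0.6, 1))
  expect_error(fit_dose_response(withzero), "t > 0")
})

test_that("dose-response t_mid tracks Gompertz-truth t_mid under model mismatch", {
  curve <- make_gompertz_curve(s_dvp = 0.043, lambda = 110)
  fit <- fit_dose_response(curve)
  expect_lt(abs(fit$t_mid - gompertz_tmid(0.043, 110)), 3)
})

test_that("logit_transform maps interior points and excludes endpoints", {
  curve <- normalized_curve(0, seq(8, 56, by = 8),
                            c(0, 0.1, 0.5, 0.890, 0.95, 0.99, 1))
  pts <- logit_transform(curve)
  expect_equal(nrow(pts), 5L)
  expect_equal(attr(pts, "n_excluded"), 2L)
  expect_equal(pts$y_logit[pts$time == 24], 0)
  expect_equal(pts$y_logit[pts$time == 32], log(0.890 / 0.110),
               tolerance = 1e-12)
  expect_equal(log(0.890 / 0.110), 2.090, tolerance = 1e-3)

  endpoints <- normalized_curve(0, c(8, 16, 24, 32), c(0, 0, 0.5, 1))
  expect_error(logit_transform(endpoints), "fewer than 2")
})

test_that("fit_logit_linear recovers exact lines and logistic curves", {
  t <- seq(100, 160, by = 8)
  pts <- data.frame(time = t, y_logit = 0.1 * (t - 120))
  fit <- fit_logit_linear(pts)
  expect_equal(fit$s_dvp, 0.1, tolerance = 1e-12)
  expect_equal(fit$t_mid, 120, tolerance = 1e-9)

  # logistic truth mirrors the published 0 M logit row
  a <- 0.106
  tm <- 123.5
  times <- seq(96, 200, by = 8)
  y <- stats::plogis(a * (times - tm))
  y[length(y)] <- 1   # normalized curves end at exactly 1
  curve <- normalized_curve(0, times, cummax(y))
  fit2 <- fit_logit_linear(logit_transform(curve))
  expect_lt(abs(fit2$s_dvp - a), 1e-6)
  expect_lt(abs(fit2$t_mid - tm), 1e-4)
  expect_gt(fit2$r2, 1 - 1e-10)

  two <- data.frame(time = c(100, 120), y_logit = c(-1, 1))
  f2 <- fit_logit_linear(two)
  expect_equal(f2$s_dvp, 0.1)
  expect_equal(f2$t_mid, 110)

  down <- data.frame(time = c(100, 120, 140), y_logit = c(1, 0, -1))
  expect_error(fit_logit_linear(down), "not positive")
})

test_that("goodness_of_fit matches hand-computed diagnostics", {
  perfect <- goodness_of_fit(c(0, 0.5, 1), c(0, 0.5, 1), k = 2)
  expect_equal(perfect$sse, 0)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$nrmse, 0)

  g <- goodness_of_fit(c(0, 0.5, 1), c(0.1, 0.5, 0.9), k = 2)
  expect_equal(g$sse, 0.02)
  expect_equal(g$r2, 0.96)
  expect_equal(g$nrmse, 16.33, tolerance = 1e-3)

  meanpred <- goodness_of_fit(c(0, 0.5, 1), rep(0.5, 3), k = 1)
  expect_equal(meanpred$r2, 0)

  expect_warning(g0 <- goodness_of_fit(c(1, 1, 1), c(1, 1, 0.9), k = 1),
                 "undefined")
  expect_true(is.na(g0$r2))
})

test_that("fitting is invariant to row order of the input file", {
  truth <- build_truth(seed = 21L)
  vials <- generate_experiment(truth)$vials
  path <- withr::local_tempfile(fileext = ".csv")
  write_counts_csv(vials, path)
  df <- read.csv(path)
  shuffled <- withr::local_tempfile(fileext = ".csv")
  set.seed(8)
  write.csv(df[sample(nrow(df)), ], shuffled, row.names = FALSE)
  fit_from <- function(p) {
    v <- read_counts_csv(p)
    fit_gompertz(normalize_curve(aggregate_replicates(v, 0.3)))
  }
  f1 <- fit_from(path)
  f2 <- fit_from(shuffled)
  expect_equal(f1$s_dvp, f2$s_dvp, tolerance = 1e-12)
  expect_equal(f1$t_mid, f2$t_mid, tolerance = 1e-12)
})

test_that("the three models agree on t_mid for a clean simulated curve", {
  # count-based data: interior proportions are bounded away from 0 and 1,
  # which keeps the logit regression's leverage realistic
  truth <- build_truth(seed = 27L)
  vials <- generate_experiment(truth)$vials
  curve <- normalize_curve(aggregate_replicates(vials, 0))
  tg <- fit_gompertz(curve)$t_mid
  dcurve <- normalized_curve(0, curve$times[curve$times > 0],
                             curve$y[curve$times > 0])
  td <- fit_dose_response(dcurve)$t_mid
  tl <- fit_logit_linear(logit_transform(curve))$t_mid
  expect_lt(max(tg, td, tl) - min(tg, td, tl), 10)
})
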