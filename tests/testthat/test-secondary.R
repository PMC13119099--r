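test_that("fit_linear matches closed-form OLS", {
  f <- fit_linear(c(0, 1, 2), c(1, 2, 4))
  expect_equal(f$coef[["a"]], 1.5)
  expect_equal(f$coef[["b"]], 5 / 6, tolerance = 1e-4)

  exact <- fit_linear(ref_conc, 2 * ref_conc + 1)
  expect_equal(exact$coef[["a"]], 2, tolerance = 1e-12)
  expect_equal(exact$coef[["b"]], 1, tolerance = 1e-12)
  expect_equal(exact$sse, 0, tolerance = 1e-25)

  flat <- fit_linear(ref_conc, rep(3, 11))
  expect_equal(flat$coef[["a"]], 0)
  expect_equal(flat$coef[["b"]], 3)

  expect_error(fit_linear(rep(1, 5), 1:5), "distinct x")
})

test_that("breakpoint_from_lines solves the intersection", {
  expect_equal(breakpoint_from_lines(1, 0, 0, 1), 1)
  # published synchrony reaction norm: intersection reproduces the
  # reported 0.581 M stress threshold
  expect_equal(breakpoint_from_lines(-0.0466, 0.0427, -0.0053, 0.018704),
               0.581, tolerance = 1e-3)
  # symmetric under swapping the two lines
  expect_equal(breakpoint_from_lines(-0.0053, 0.018704, -0.0466, 0.0427),
               breakpoint_from_lines(-0.0466, 0.0427, -0.0053, 0.018704))
  expect_error(breakpoint_from_lines(2, 0, 2, 1), "parallel")
})

test_that("breakpoint_from_lines is equivariant under affine rescaling of x", {
  set.seed(4)
  for (rep in 1:20) {
    a1 <- rnorm(1); b1 <- rnorm(1); a2 <- rnorm(1); b2 <- rnorm(1)
    if (a1 == a2) next
    s <- runif(1, 0.5, 3); d <- rnorm(1)
    xc <- breakpoint_from_lines(a1, b1, a2, b2)
    # x' = s*x + d  =>  line y = a x + b becomes y = (a/s) x' + (b - a d / s)
    xc2 <- breakpoint_from_lines(a1 / s, b1 - a1 * d / s,
                                 a2 / s, b2 - a2 * d / s)
    expect_equal(xc2, s * xc + d, tolerance = 1e-9)
  }
})

test_that("fit_bilinear recovers exact piecewise data to machine precision", {
  y <- ifelse(ref_conc <= 0.6, 0.04 - 0.05 * ref_conc,
              0.013 - 0.005 * ref_conc)
  fit <- suppressWarnings(fit_bilinear(ref_conc, y))   # SSE = 0 warns on AIC
  expect_false(fit$fallback)
  expect_equal(fit$coef[["a1"]], -0.05, tolerance = 1e-12)
  expect_equal(fit$coef[["b1"]], 0.04, tolerance = 1e-12)
  expect_equal(fit$coef[["a2"]], -0.005, tolerance = 1e-12)
  expect_equal(fit$coef[["b2"]], 0.013, tolerance = 1e-12)
  expect_equal(fit$x_c, 0.6, tolerance = 1e-9)
  expect_error(fit_bilinear(ref_conc[1:4], y[1:4]), "at least 5")
})

test_that("fit_bilinear on the published synchrony row finds the stress threshold", {
  fit <- fit_bilinear(ref_conc, ref_sdvp_gompertz)
  expect_lt(abs(fit$x_c - 0.581), 0.02)
  expect_gt(fit$r2, 0.98)
})

test_that("fit_bilinear equals the exhaustive-enumeration oracle on random data", {
  set.seed(12)
  n_checked <- 0L
  for (rep in 1:200) {
    kind <- rep %% 3
    y <- if (kind == 0) {
      # genuinely kinked
      xc <- runif(1, 0.2, 1.3)
      a1 <- rnorm(1, 0, 0.05); a2 <- rnorm(1, 0, 0.05); b1 <- rnorm(1, 0.04, 0.02)
      ifelse(ref_conc <= xc, a1 * ref_conc + b1,
             a2 * ref_conc + b1 + (a1 - a2) * xc) + rnorm(11, 0, 0.002)
    } else if (kind == 1) {
      rnorm(11, 0, 1)                    # pure noise
    } else {
      -0.02 * ref_conc + 0.04 + rnorm(11, 0, 0.003)   # linear-ish
    }
    oracle <- brute_force_bilinear(ref_conc, y)
    if (is.null(oracle)) next            # no admissible candidate
    n_checked <- n_checked + 1L
    fit <- suppressWarnings(fit_bilinear(ref_conc, y))
    expect_false(fit$fallback)
    expect_equal(fit$x_c, oracle$xc, tolerance = 1e-10)
    expect_equal(fit$sse, oracle$sse, tolerance = 1e-10)
    expect_equal(unname(fit$coef),
                 c(oracle$a1, oracle$b1, oracle$a2, oracle$b2),
                 tolerance = 1e-9)
    # the two-segment model can only improve on the single line
    lin <- fit_linear(ref_conc, y)
    expect_lte(fit$sse, lin$sse + 1e-12)
  }
  expect_gt(n_checked, 120)
})

test_that("aic_from_sse implements the SSE-based criterion", {
  expect_equal(aic_from_sse(7, 7, 2), 4)
  expect_equal(aic_from_sse(1e-4, 11, 4), -119.66, tolerance = 0.01)
  # strictly increasing in SSE at fixed n, k
  sses <- c(0.5, 1, 2, 5)
  aics <- vapply(sses, aic_from_sse, numeric(1), n = 11, k = 4)
  expect_true(all(diff(aics) > 0))
  expect_warning(a0 <- aic_from_sse(0, 11, 4), "perfect fit")
  expect_identical(a0, -Inf)
})

test_that("AIC comparison favors bilinear on kinked data, linear truth mostly not", {
  cmp <- compare_linear_bilinear(ref_conc, ref_sdvp_gompertz)
  expect_gt(cmp$delta_aic, 2)

  # under a straight-line truth with the reference residual scale the
  # spurious-kink selection rate stays bounded (established at 0.284 for
  # this exact seeded run)
  set.seed(42)
  n_sup <- 0L
  for (rep in 1:500) {
    y <- -0.02 * ref_conc + 0.04 + rnorm(11, 0, 0.0011)
    if (suppressWarnings(compare_linear_bilinear(ref_conc, y))$delta_aic > 2)
      n_sup <- n_sup + 1L
  }
  expect_lt(n_sup / 500, 0.35)

  expect_error(compare_linear_bilinear(ref_conc[1:3], ref_sdvp_gompertz[1:3]),
               "at least")
})

test_that("residual bootstrap is deterministic and degenerates sensibly", {
  y <- ifelse(ref_conc <= 0.6, 0.04 - 0.05 * ref_conc,
              0.013 - 0.005 * ref_conc)
  # zero residuals: every resample refits the same data
  b0 <- suppressWarnings(
    residual_bootstrap_bilinear(ref_conc, y, n_boot = 50, seed = 3))
  expect_true(all(abs(b0$ci$upper - b0$ci$lower) < 1e-9))
  expect_equal(b0$ci$point[b0$ci$statistic == "x_c"], 0.6, tolerance = 1e-9)

  b1 <- residual_bootstrap_bilinear(ref_conc, ref_sdvp_gompertz,
                                    n_boot = 200, seed = 9)
  b2 <- residual_bootstrap_bilinear(ref_conc, ref_sdvp_gompertz,
                                    n_boot = 200, seed = 9)
  expect_identical(b1$ci, b2$ci)
  b3 <- residual_bootstrap_bilinear(ref_conc, ref_sdvp_gompertz,
                                    n_boot = 200, seed = 10)
  expect_false(identical(b1$ci$lower, b3$ci$lower))
  # point estimates bracketed by percentile bounds on well-behaved data
  xc_row <- b1$ci[b1$ci$statistic == "x_c", ]
  expect_lte(xc_row$lower, xc_row$point)
  expect_gte(xc_row$upper, xc_row$point)
})
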