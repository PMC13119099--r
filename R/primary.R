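# Primary sigmoid models for normalized developmental curves.
#
# All three models describe the normalized cumulative response y in [0, 1]
# as a function of time t (hours). Two parameters are extracted from each:
#   t_mid  - mean developmental time, where the curve crosses 0.5
#   s_dvp  - developmental synchrony: for the Gompertz model the maximum
#            rate of the curve (1/h); for the logit linearization the slope
#            of the logit line (1/h); for the log-dose logistic a
#            dimensionless log10-time steepness.

.E <- exp(1)

.new_primary_fit <- function(model, s_dvp, t_mid, lambda = NA_real_,
                             gof, n_points, n_excluded = 0L) {
  structure(
    list(model = model, s_dvp = s_dvp, t_mid = t_mid, lambda = lambda,
         sse = gof[["sse"]], r2 = gof[["r2"]], nrmse = gof[["nrmse"]],
         n_points = n_points, n_excluded = n_excluded),
    class = "primary_fit")
}

#' @export
print.primary_fit <- function(x, ...) {
  cat(sprintf("<primary_fit:%s>  s_dvp=%.4g  t_mid=%.4g h%s\n",
              x$model, x$s_dvp, x$t_mid,
              if (is.finite(x$lambda)) sprintf("  lambda=%.4g h", x$lambda) else ""))
  cat(sprintf("  n=%d  SSE=%.3g  R2=%.4f  nRMSE=%.2f%%\n",
              x$n_points, x$sse, x$r2, x$nrmse))
  invisible(x)
}

#' Gompertz developmental curve
#'
#' Normalized Gompertz sigmoid
#' `y(t) = exp(-exp(s_dvp * e * (lambda - t) + 1))`,
#' with `y0 = 0` and `y_max = 1` fixed as appropriate for curves normalized
#' to their final value. `s_dvp` equals the maximum slope of the curve
#' (attained where y = 1/e) and `lambda` is the lag time before the first
#' pupariation or eclosion events. The unnormalized four-parameter form is
#' available through `y0` and `y_max`.
#'
#' @param t Time(s) in hours; any real value.
#' @param s_dvp Synchrony parameter, the maximum developmental rate (1/h), > 0.
#' @param lambda Lag time (hours).
#' @param y0,y_max Optional lower/upper asymptotes of the generalized curve;
#'   the defaults give the normalized form used throughout the package.
#'
#' @return Predicted response, same length as `t`.
#' @export
gompertz_predict <- function(t, s_dvp, lambda, y0 = 0, y_max = 1) {
  if (!is.numeric(s_dvp) || s_dvp <= 0) .stopf("s_dvp must be > 0")
  if (y_max <= y0) .stopf("y_max must exceed y0")
  y0 + (y_max - y0) * exp(-exp(s_dvp / (y_max - y0) * .E * (lambda - t) + 1))
}

#' Closed-form mean developmental time of the Gompertz curve
#'
#' Solves `gompertz_predict(t) = 1/2` for t:
#' `t_mid = lambda + (1 - log(log(2))) / (e * s_dvp)`.
#'
#' @param s_dvp Synchrony parameter (1/h), > 0.
#' @param lambda Lag time (hours).
#'
#' @return `t_mid` in hours.
#' @export
gompertz_tmid <- function(s_dvp, lambda) {
  if (!is.numeric(s_dvp) || any(s_dvp <= 0)) .stopf("s_dvp must be > 0")
  lambda + (1 - log(log(2))) / (.E * s_dvp)
}

#' Lag time implied by a Gompertz mean time and synchrony
#'
#' Inverse of [gompertz_tmid()]; used by the synthetic-data generator to
#' back-compute `lambda` from ground-truth reaction norms for `t_mid` and
#' `s_dvp`.
#'
#' @param s_dvp Synchrony parameter (1/h), > 0.
#' @param t_mid Mean developmental time (hours).
#'
#' @return `lambda` in hours.
#' @export
gompertz_lambda <- function(s_dvp, t_mid) {
  if (!is.numeric(s_dvp) || any(s_dvp <= 0)) .stopf("s_dvp must be > 0")
  t_mid - (1 - log(log(2))) / (.E * s_dvp)
}

#' Log-dose logistic developmental curve
#'
#' The dose-response form borrowed from pharmacology, with log10 time in the
#' role of log dose:
#' `y(t) = 1 / (1 + 10^(-s_dvp * (log10(t) - log10(t_mid))))`.
#' `s_dvp` here is a dimensionless steepness on the log10-time axis and
#' `t_mid` is the time at which y = 0.5 exactly.
#'
#' @param t Time(s) in hours, strictly positive.
#' @param s_dvp Steepness (dimensionless), > 0.
#' @param t_mid Mean developmental time (hours), > 0.
#'
#' @return Predicted response, same length as `t`.
#' @export
dose_response_predict <- function(t, s_dvp, t_mid) {
  if (any(t <= 0)) .stopf("dose-response curve is defined for t > 0 only")
  if (t_mid <= 0) .stopf("t_mid must be > 0")
  if (s_dvp <= 0) .stopf("s_dvp must be > 0")
  1 / (1 + 10^(-s_dvp * (log10(t) - log10(t_mid))))
}

#' Logit transform of a normalized curve
#'
#' Maps interior points of the normalized curve onto the unbounded logit
#' scale, `y_logit = log(y / (1 - y))`, so a logistic developmental curve
#' becomes a straight line in time. Points with y = 0 or y = 1 have no
#' finite logit and are excluded; their count is attached as the
#' `n_excluded` attribute and reported downstream.
#'
#' @param curve A [normalized_curve].
#'
#' @return A data.frame with columns `time` and `y_logit`, with attribute
#'   `n_excluded`.
#' @export
logit_transform <- function(curve) {
  stopifnot(inherits(curve, "normalized_curve"))
  keep <- curve$y > 0 & curve$y < 1
  if (sum(keep) < 2L)
    .stopf("fewer than 2 points with 0 < y < 1 at %g M: cannot regress on the logit scale",
           curve$concentration)
  out <- data.frame(time = curve$times[keep],
                    y_logit = log(curve$y[keep] / (1 - curve$y[keep])))
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Goodness-of-fit diagnostics
#'
#' Returns the sum of squared errors, the coefficient of determination
#' `R2 = 1 - SSE / SStot`, and the normalized root-mean-square error
#' `nRMSE = 100 * sqrt(SSE / n) / mean(observed)` (percent of the observed
#' mean).
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2).
#' @param k Number of fitted parameters (recorded for downstream AIC use).
#'
#' @return Named list with `sse`, `r2`, `nrmse`, `n`, `k`.
#' @export
goodness_of_fit <- function(observed, predicted, k) {
  n <- length(observed)
  if (n < 2L || length(predicted) != n)
    .stopf("observed and predicted must have equal length >= 2")
  sse <- sum((observed - predicted)^2)
  sstot <- sum((observed - mean(observed))^2)
  if (sstot <= 0) {
    .warnf("observed values are all equal; R2 is undefined")
    r2 <- NA_real_
  } else {
    r2 <- 1 - sse / sstot
  }
  m <- mean(observed)
  nrmse <- if (m == 0) NA_real_ else 100 * sqrt(sse / n) / m
  list(sse = sse, r2 = r2, nrmse = nrmse, n = n, k = k)
}

.check_fittable <- function(curve, min_points) {
  if (length(curve$y) < min_points)
    .stopf("need at least %d points to fit, got %d", min_points,
           length(curve$y))
  if (!any(curve$y > 0 & curve$y < 1))
    .stopf("degenerate curve at %g M: no points strictly between 0 and 1",
           curve$concentration)
}

#' Fit the Gompertz model to a normalized curve
#'
#' Nonlinear least squares (bounded Levenberg-Marquardt via
#' [minpack.lm::nlsLM()]) for `(s_dvp, lambda)`, with `t_mid` filled in from
#' the closed form [gompertz_tmid()]. Initialization is deterministic:
#' `lambda` starts at the last observation time with y = 0 (the first time
#' if the curve never sits at 0) and `s_dvp` at the maximum finite-difference
#' slope of the curve.
#'
#' @param curve A [normalized_curve].
#'
#' @return A `primary_fit` object (model `"gompertz"`).
#' @export
fit_gompertz <- function(curve) {
  stopifnot(inherits(curve, "normalized_curve"))
  .check_fittable(curve, 4L)
  t <- curve$times
  y <- curve$y
  slopes <- diff(y) / diff(t)
  s0 <- max(slopes)
  if (s0 <= 0) s0 <- 0.01
  zero <- t[y == 0]
  l0 <- if (length(zero)) max(zero) else t[1L]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ exp(-exp(s * exp(1) * (l - t) + 1)),
      data = data.frame(t = t, y = y),
      start = list(s = s0, l = l0),
      lower = c(1e-6, 0), upper = c(Inf, max(t)),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10)),
    error = function(e)
      .stopf("Gompertz fit failed to converge at %g M (start s=%.3g, lambda=%.3g): %s",
             curve$concentration, s0, l0, conditionMessage(e)))
  cf <- stats::coef(fit)
  pred <- gompertz_predict(t, cf[["s"]], cf[["l"]])
  .new_primary_fit("gompertz", s_dvp = cf[["s"]],
                   t_mid = gompertz_tmid(cf[["s"]], cf[["l"]]),
                   lambda = cf[["l"]],
                   gof = goodness_of_fit(y, pred, k = 2L),
                   n_points = length(y))
}

#' Fit the log-dose logistic model to a normalized curve
#'
#' Nonlinear least squares for `(s_dvp, t_mid)` of
#' [dose_response_predict()]. All observation times must be strictly
#' positive, since the model lives on a log10-time axis.
#'
#' @param curve A [normalized_curve].
#'
#' @return A `primary_fit` object (model `"dose_response"`).
#' @export
fit_dose_response <- function(curve) {
  stopifnot(inherits(curve, "normalized_curve"))
  if (any(curve$times <= 0))
    .stopf("dose-response fit requires t > 0 at every point (curve at %g M has t = %g)",
           curve$concentration, min(curve$times))
  .check_fittable(curve, 3L)
  t <- curve$times
  y <- curve$y
  tm0 <- t[which.min(abs(y - 0.5))]
  smax <- max(diff(y) / diff(t))
  # slope at the midpoint of the log-dose logistic is s*log(10)/(4*t_mid)
  s0 <- max(4 * tm0 * smax / log(10), 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ 1 / (1 + 10^(-s * (log10(t) - log10(tm)))),
      data = data.frame(t = t, y = y),
      start = list(s = s0, tm = tm0),
      lower = c(1e-6, min(t)), upper = c(Inf, max(t)),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10)),
    error = function(e)
      .stopf("dose-response fit failed to converge at %g M: %s",
             curve$concentration, conditionMessage(e)))
  cf <- stats::coef(fit)
  pred <- dose_response_predict(t, cf[["s"]], cf[["tm"]])
  .new_primary_fit("dose_response", s_dvp = cf[["s"]], t_mid = cf[["tm"]],
                   gof = goodness_of_fit(y, pred, k = 2L),
                   n_points = length(y))
}

#' Fit a line to logit-transformed curve points
#'
#' Ordinary least squares of `y_logit` on time. The slope is the synchrony
#' parameter `s_dvp` and the x-intercept `-b/a` is `t_mid` (the time where
#' the logit crosses 0, i.e. y = 0.5). Goodness-of-fit diagnostics are
#' computed on the back-transformed probability scale so they are comparable
#' with the other primary models (logit-scale residuals have mean near zero,
#' which makes a mean-normalized RMSE meaningless).
#'
#' @param points Data frame from [logit_transform()] (columns `time`,
#'   `y_logit`).
#'
#' @return A `primary_fit` object (model `"logit"`).
#' @export
fit_logit_linear <- function(points) {
  if (nrow(points) < 2L || length(unique(points$time)) < 2L)
    .stopf("need at least 2 points with distinct times for the logit regression")
  cf <- .ols(points$time, points$y_logit)
  a <- cf[1L]
  b <- cf[2L]
  if (a <= 0)
    .stopf("logit regression slope is not positive (%.3g): curve is not developing",
           a)
  obs_y <- stats::plogis(points$y_logit)
  pred_y <- stats::plogis(a * points$time + b)
  n_exc <- attr(points, "n_excluded")
  .new_primary_fit("logit", s_dvp = a, t_mid = -b / a,
                   gof = goodness_of_fit(obs_y, pred_y, k = 2L),
                   n_points = nrow(points),
                   n_excluded = if (is.null(n_exc)) 0L else n_exc)
}
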