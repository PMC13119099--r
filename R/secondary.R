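# Secondary models: reaction norms of the primary parameters over sucrose
# concentration. A linear and a two-segment (bilinear) model are fitted and
# compared by SSE-based AIC; uncertainty in the bilinear breakpoint comes
# from a residual bootstrap.

.new_secondary_fit <- function(parameter, model, coef, x_c = NA_real_,
                               split = NA_integer_, fallback = FALSE,
                               gof, aic) {
  structure(
    list(parameter = parameter, model = model, coef = coef, x_c = x_c,
         split = split, fallback = fallback,
         sse = gof[["sse"]], aic = aic, r2 = gof[["r2"]],
         nrmse = gof[["nrmse"]], n_points = gof[["n"]], k = gof[["k"]]),
    class = "secondary_fit")
}

#' @export
print.secondary_fit <- function(x, ...) {
  if (x$model == "linear") {
    cat(sprintf("<secondary_fit:linear> %s  y = %.4g x + %.4g\n",
                x$parameter, x$coef[["a"]], x$coef[["b"]]))
  } else {
    cat(sprintf("<secondary_fit:bilinear> %s  x_c = %.4g M%s\n",
                x$parameter, x$x_c, if (x$fallback) " (fallback)" else ""))
    cat(sprintf("  left:  y = %.4g x + %.4g\n  right: y = %.4g x + %.4g\n",
                x$coef[["a1"]], x$coef[["b1"]], x$coef[["a2"]], x$coef[["b2"]]))
  }
  cat(sprintf("  n=%d k=%d  SSE=%.4g  AIC=%.2f  R2=%.4f  nRMSE=%.2f%%\n",
              x$n_points, x$k, x$sse, x$aic, x$r2, x$nrmse))
  invisible(x)
}

#' AIC from a sum of squared errors
#'
#' The least-squares information criterion `AIC = n * log(SSE / n) + 2k`
#' (no small-sample correction, no additive constants), appropriate for
#' comparing models fitted to the same data by SSE minimization.
#'
#' @param sse Sum of squared errors, > 0.
#' @param n Number of data points.
#' @param k Number of fitted parameters.
#'
#' @return The AIC value; `-Inf` with a warning when `sse == 0`.
#' @export
aic_from_sse <- function(sse, n, k) {
  if (n <= 0) .stopf("n must be positive")
  if (sse < 0) .stopf("sse must be non-negative")
  if (sse == 0) {
    .warnf("SSE is zero (perfect fit); AIC is -Inf")
    return(-Inf)
  }
  n * log(sse / n) + 2 * k
}

#' Fit a linear reaction norm
#'
#' Ordinary least squares of a primary parameter on sucrose concentration,
#' `y = a x + b`.
#'
#' @param x Concentrations (mol/L).
#' @param y Parameter values (same length).
#' @param parameter Optional label (`"s_dvp"` or `"t_mid"`) carried into the
#'   result.
#'
#' @return A `secondary_fit` object (model `"linear"`).
#' @export
fit_linear <- function(x, y, parameter = NA_character_) {
  if (length(x) != length(y)) .stopf("x and y must have equal length")
  if (length(unique(x)) < 2L) .stopf("need at least 2 distinct x values")
  cf <- .ols(x, y)
  pred <- cf[1L] * x + cf[2L]
  gof <- goodness_of_fit(y, pred, k = 2L)
  .new_secondary_fit(parameter, "linear", coef = c(a = cf[1L], b = cf[2L]),
                     gof = gof, aic = aic_from_sse(gof$sse, gof$n, 2L))
}

#' Intersection of two lines
#'
#' The breakpoint of a bilinear model is where its two segments meet:
#' solving `a1 * x_c + b1 = a2 * x_c + b2` gives
#' `x_c = (b2 - b1) / (a1 - a2)`.
#'
#' @param a1,b1 Slope and intercept of the first line.
#' @param a2,b2 Slope and intercept of the second line.
#'
#' @return The crossing point `x_c`.
#' @export
breakpoint_from_lines <- function(a1, b1, a2, b2) {
  if (a1 == a2) .stopf("lines are parallel (a1 == a2): no breakpoint")
  (b2 - b1) / (a1 - a2)
}

# Enumerate all two-block splits of (sorted) x, fit OLS per block, and score
# each candidate. Shared by fit_bilinear and the bootstrap refits.
# A candidate is admissible when its x_c is consistent with the partition it
# was fitted on: with the left segment defined on x <= x_c, that is
# xs[m] <= x_c < xs[m+1] (left-closed, so a kink sitting exactly on a grid
# point is recovered; a small tolerance absorbs floating-point error).
# Returns list(best admissible, best overall-with-clamped-xc).
.bilinear_search <- function(xs, ys) {
  n <- length(xs)
  tol <- 1e-9 * (xs[n] - xs[1L])
  best <- NULL
  best_any <- NULL
  for (m in 2:(n - 2L)) {
    li <- seq_len(m)
    cl <- .ols(xs[li], ys[li])
    cr <- .ols(xs[-li], ys[-li])
    denom <- cl[1L] - cr[1L]
    x_c <- if (denom == 0) NA_real_ else (cr[2L] - cl[2L]) / denom
    admissible <- is.finite(x_c) && x_c >= xs[m] - tol && x_c < xs[m + 1L]
    x_use <- if (admissible) x_c else (xs[m] + xs[m + 1L]) / 2
    pred <- ifelse(xs <= x_use, cl[1L] * xs + cl[2L], cr[1L] * xs + cr[2L])
    sse <- sum((ys - pred)^2)
    cand <- list(m = m, a1 = cl[1L], b1 = cl[2L], a2 = cr[1L], b2 = cr[2L],
                 x_c = x_use, sse = sse, pred = pred,
                 admissible = admissible)
    if (admissible && (is.null(best) || sse < best$sse)) best <- cand
    if (is.null(best_any) || sse < best_any$sse) best_any <- cand
  }
  list(best = best, fallback = best_any)
}

#' Fit a bilinear (two-segment) reaction norm
#'
#' Deterministic global fit of the two-line model
#' `y = a1 x + b1` for `x <= x_c`, `y = a2 x + b2` for `x > x_c`,
#' with the breakpoint defined as the intersection of the two fitted lines.
#' Every split of the sorted concentrations into a left and right block of
#' at least 2 points is enumerated; each block is fitted by OLS and the
#' candidate is admissible when the implied `x_c` falls between the blocks'
#' adjoining x values (closed on the left, so the piecewise assignment
#' `x <= x_c` is consistent with the partition the lines were fitted on).
#' The admissible candidate
#' with the smallest total SSE of the piecewise prediction wins; SSE ties
#' are broken by the smaller split index. If no candidate is admissible the
#' minimum-SSE split is returned with `x_c` clamped to the midpoint of its
#' bracket and flagged via `fallback = TRUE`.
#'
#' @param x Concentrations (mol/L), at least 5 values.
#' @param y Parameter values (same length).
#' @param parameter Optional label carried into the result.
#'
#' @return A `secondary_fit` object (model `"bilinear"`) with coefficients
#'   `a1, b1, a2, b2`, breakpoint `x_c`, and diagnostics (`k = 4`).
#' @export
fit_bilinear <- function(x, y, parameter = NA_character_) {
  if (length(x) != length(y)) .stopf("x and y must have equal length")
  n <- length(x)
  if (n < 5L)
    .stopf("need at least 5 points for a bilinear fit (2 per segment plus identification), got %d",
           n)
  o <- order(x)
  xs <- x[o]
  ys <- y[o]
  res <- .bilinear_search(xs, ys)
  cand <- res$best
  fallback <- FALSE
  if (is.null(cand)) {
    cand <- res$fallback
    fallback <- TRUE
    .warnf("no admissible breakpoint (every intersection falls outside its bracket); using minimum-SSE split with x_c clamped to the bracket midpoint")
  }
  gof <- goodness_of_fit(ys, cand$pred, k = 4L)
  .new_secondary_fit(
    parameter, "bilinear",
    coef = c(a1 = cand$a1, b1 = cand$b1, a2 = cand$a2, b2 = cand$b2),
    x_c = cand$x_c, split = cand$m, fallback = fallback,
    gof = gof, aic = aic_from_sse(gof$sse, gof$n, 4L))
}

#' Predict from a fitted secondary model
#'
#' @param object A `secondary_fit`.
#' @param newdata Concentrations at which to predict (numeric vector).
#' @param ... Unused.
#'
#' @return Predicted parameter values.
#' @export
predict.secondary_fit <- function(object, newdata, ...) {
  cf <- object$coef
  if (object$model == "linear") {
    cf[["a"]] * newdata + cf[["b"]]
  } else {
    ifelse(newdata <= object$x_c,
           cf[["a1"]] * newdata + cf[["b1"]],
           cf[["a2"]] * newdata + cf[["b2"]])
  }
}

#' Compare linear and bilinear reaction norms by AIC
#'
#' Fits both models to the same data and reports
#' `delta_aic = AIC(linear) - AIC(bilinear)`; positive values favor the
#' bilinear model, and `delta_aic > 2` is the conventional support
#' threshold.
#'
#' @inheritParams fit_bilinear
#'
#' @return A list with elements `linear`, `bilinear` (both `secondary_fit`)
#'   and `delta_aic`.
#' @export
compare_linear_bilinear <- function(x, y, parameter = NA_character_) {
  lin <- fit_linear(x, y, parameter)
  bil <- fit_bilinear(x, y, parameter)
  list(linear = lin, bilinear = bil, delta_aic = lin$aic - bil$aic)
}

#' Residual bootstrap confidence intervals for the bilinear fit
#'
#' Residuals of the fitted piecewise model (pooled across both segments) are
#' resampled with replacement, added back to the fitted values, and the full
#' split-enumeration fit is repeated on each resample. Percentile 2.5/97.5
#' bounds are reported for the breakpoint and the four line coefficients.
#' Each resample uses an RNG stream derived from `seed` by a counter offset,
#' so results are bit-reproducible and independent of iteration order.
#' Resamples whose refit has no admissible breakpoint fall back to the
#' clamped-midpoint estimate (counted in `n_fallback`); resamples whose
#' refit fails outright are dropped and counted, and more than 20% failures
#' is an error.
#'
#' @param x Concentrations (mol/L).
#' @param y Parameter values.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer root seed.
#' @param level Confidence level (default 0.95).
#' @param parameter Optional label carried into the result.
#'
#' @return An object of class `bilinear_bootstrap`: a list with `ci` (a
#'   data.frame with one row per statistic: point estimate, lower, upper),
#'   `level`, `n_boot`, `seed`, `n_fallback`, `n_failed`, and the base
#'   `fit`.
#' @export
residual_bootstrap_bilinear <- function(x, y, n_boot = 1000L, seed = 1L,
                                        level = 0.95,
                                        parameter = NA_character_) {
  if (n_boot < 1L) .stopf("n_boot must be >= 1")
  fit0 <- fit_bilinear(x, y, parameter)
  o <- order(x)
  xs <- x[o]
  ys <- y[o]
  fitted0 <- predict(fit0, xs)
  res <- ys - fitted0
  n <- length(xs)
  stats_names <- c("x_c", "a1", "b1", "a2", "b2")
  draws <- matrix(NA_real_, nrow = n_boot, ncol = 5L,
                  dimnames = list(NULL, stats_names))
  n_fallback <- 0L
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    # counter-offset stream: distinct root seeds must not share resamples,
    # so the counter is spread by a large prime before mixing with the seed
    yb <- .with_seed(as.numeric(seed) * 1000003 + b * 7919,
                     fitted0 + sample(res, n, replace = TRUE))
    sr <- tryCatch(.bilinear_search(xs, yb), error = function(e) NULL)
    if (is.null(sr)) {
      n_failed <- n_failed + 1L
      next
    }
    cand <- sr$best
    if (is.null(cand)) {
      cand <- sr$fallback
      n_fallback <- n_fallback + 1L
    }
    draws[b, ] <- c(cand$x_c, cand$a1, cand$b1, cand$a2, cand$b2)
  }
  if (n_failed > 0.2 * n_boot)
    .stopf("%d of %d bootstrap refits failed (> 20%%)", n_failed, n_boot)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  point <- c(fit0$x_c, fit0$coef[["a1"]], fit0$coef[["b1"]],
             fit0$coef[["a2"]], fit0$coef[["b2"]])
  qs <- apply(draws, 2L, stats::quantile, probs = probs, na.rm = TRUE)
  ci <- data.frame(statistic = stats_names, point = point,
                   lower = qs[1L, ], upper = qs[2L, ],
                   row.names = NULL, stringsAsFactors = FALSE)
  structure(
    list(ci = ci, level = level, n_boot = as.integer(n_boot),
         seed = as.integer(seed), n_fallback = n_fallback,
         n_failed = n_failed, fit = fit0),
    class = "bilinear_bootstrap")
}

#' @export
print.bilinear_bootstrap <- function(x, ...) {
  cat(sprintf("<bilinear_bootstrap> %d resamples, seed %d, %.0f%% percentile intervals\n",
              x$n_boot, x$seed, 100 * x$level))
  if (x$n_fallback > 0L)
    cat(sprintf("  %d refits used the clamped-midpoint fallback\n", x$n_fallback))
  if (x$n_failed > 0L)
    cat(sprintf("  %d refits failed and were dropped\n", x$n_failed))
  print(transform(x$ci, point = signif(point, 4), lower = signif(lower, 4),
                  upper = signif(upper, 4)))
  invisible(x)
}
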