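# Synthetic vial-count experiments with known ground truth.
#
# The generator emulates the embryo-to-pupa assay design: a grid of sucrose
# concentrations, several replicate vials of n_embryos each, survivors drawn
# binomially, individual pupariation times drawn from the Gompertz curve
# read as a cumulative distribution, and observation censored onto a
# periodic grid.

.eval_bilinear_norm <- function(norm, x) {
  ifelse(x <= norm$x_c,
         norm$a1 * x + norm$b1,
         norm$a2 * x + norm$b2)
}

#' Bilinear reaction norm specification
#'
#' Ground-truth reaction norm for the simulator: two line segments meeting
#' at `x_c`. When `b2` is omitted it is derived from continuity at the
#' breakpoint, `b2 = b1 + (a1 - a2) * x_c`.
#'
#' @param a1,b1 Slope and intercept of the segment below `x_c`.
#' @param a2 Slope of the segment above `x_c`.
#' @param x_c Breakpoint (mol/L).
#' @param b2 Intercept of the upper segment; default continuous at `x_c`.
#'
#' @return An object of class `bilinear_norm`.
#' @export
bilinear_norm <- function(a1, b1, a2, x_c, b2 = NULL) {
  if (is.null(b2)) b2 <- b1 + (a1 - a2) * x_c
  structure(list(a1 = a1, b1 = b1, a2 = a2, b2 = b2, x_c = x_c),
            class = "bilinear_norm")
}

#' Assemble the ground truth for a synthetic experiment
#'
#' Resolves the full simulator configuration: the concentration grid, the
#' bilinear reaction norms for synchrony and timing, the per-concentration
#' survival probabilities, and the design constants. The Gompertz lag
#' `lambda(E)` is back-computed from `t_mid(E)` and `s_dvp(E)` through the
#' closed form, so the simulated curves have exactly the requested mean
#' times. Defaults emulate the sucrose assay: 11 concentrations 0-1.5 M in
#' 0.15 M steps, 5 vials of 50 embryos, an 8 h observation grid, a
#' synchrony norm with breakpoint 0.581 M, a timing norm with breakpoint
#' 0.524 M, and viability declining linearly from 0.85 to 0.55 across the
#' grid.
#'
#' @param concentrations Concentration grid (mol/L).
#' @param s_dvp_norm [bilinear_norm] for synchrony (1/h over mol/L).
#' @param tmid_norm [bilinear_norm] for mean developmental time (h over
#'   mol/L).
#' @param viability Either a numeric vector over the grid or a function of
#'   concentration returning survival probabilities in (0, 1].
#' @param n_vials Replicate vials per concentration.
#' @param n_embryos Embryos seeded per vial.
#' @param obs_interval_h Observation grid spacing (hours).
#' @param seed Root seed for the experiment.
#'
#' @return An object of class `synthetic_truth`.
#' @export
build_truth <- function(concentrations = seq(0, 1.5, by = 0.15),
                        s_dvp_norm = bilinear_norm(a1 = -0.0466, b1 = 0.0427,
                                                   a2 = -0.0053, x_c = 0.581),
                        tmid_norm = bilinear_norm(a1 = 40.07, b1 = 117.5,
                                                  a2 = 153.9, x_c = 0.524),
                        viability = function(E) 0.85 + (0.55 - 0.85) * E / 1.5,
                        n_vials = 5L, n_embryos = 50L, obs_interval_h = 8,
                        seed = 1L) {
  stopifnot(inherits(s_dvp_norm, "bilinear_norm"),
            inherits(tmid_norm, "bilinear_norm"))
  s <- .eval_bilinear_norm(s_dvp_norm, concentrations)
  tm <- .eval_bilinear_norm(tmid_norm, concentrations)
  if (any(s <= 0))
    .stopf("s_dvp reaction norm is non-positive at concentration %g M",
           concentrations[which(s <= 0)[1L]])
  if (any(tm <= 0))
    .stopf("t_mid reaction norm is non-positive at concentration %g M",
           concentrations[which(tm <= 0)[1L]])
  v <- if (is.function(viability)) viability(concentrations) else viability
  if (length(v) != length(concentrations) || any(v <= 0) || any(v > 1))
    .stopf("viability must give values in (0, 1] for every grid concentration")
  structure(
    list(concentrations = concentrations, s_dvp_norm = s_dvp_norm,
         tmid_norm = tmid_norm, s_dvp = s, t_mid = tm,
         lambda = gompertz_lambda(s, tm), viability = v,
         n_vials = as.integer(n_vials), n_embryos = as.integer(n_embryos),
         obs_interval_h = obs_interval_h, seed = as.integer(seed)),
    class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %d concentrations (%g-%g M), %d vials x %d embryos, %g h grid, seed %d\n",
              length(x$concentrations), min(x$concentrations),
              max(x$concentrations), x$n_vials, x$n_embryos,
              x$obs_interval_h, x$seed))
  cat(sprintf("  s_dvp breakpoint %.3f M, t_mid breakpoint %.3f M\n",
              x$s_dvp_norm$x_c, x$tmid_norm$x_c))
  invisible(x)
}

#' Draw individual pupariation times from the Gompertz curve
#'
#' Reads the normalized Gompertz curve as the cumulative distribution of
#' individual developmental times and samples by inversion:
#' `t(u) = lambda + (1 - log(-log(u))) / (e * s_dvp)` for
#' `u ~ Uniform(0, 1)`, so the empirical CDF of the sample converges to
#' [gompertz_predict()].
#'
#' @param n Number of individuals (>= 0).
#' @param s_dvp Synchrony parameter (1/h), > 0.
#' @param lambda Lag time (hours).
#' @param seed Optional seed; when given, sampling is reproducible and the
#'   caller's RNG state is untouched.
#'
#' @return Event times in hours, length `n`.
#' @export
sample_pupariation_times <- function(n, s_dvp, lambda, seed = NULL) {
  if (s_dvp <= 0) .stopf("s_dvp must be > 0")
  if (n == 0L) return(numeric(0))
  u <- if (is.null(seed)) stats::runif(n)
       else .with_seed(seed, stats::runif(n))
  lambda + (1 - log(-log(u))) / (exp(1) * s_dvp)
}

#' Simulate one vial
#'
#' Survivors are drawn binomially with the concentration's survival
#' probability, their pupariation times sampled from the Gompertz event-time
#' distribution, and the cumulative count censored onto the observation grid
#' running from 0 h to one day past the last event (so the curve attains its
#' plateau). A vial with zero survivors yields an all-zero series.
#'
#' @param concentration A concentration on the truth grid (mol/L).
#' @param truth A [build_truth()] object.
#' @param vial_seed Integer seed for this vial.
#' @param vial_id Optional identifier; a default is derived from the
#'   concentration and seed.
#'
#' @return A [vial_series].
#' @export
simulate_vial <- function(concentration, truth, vial_seed,
                          vial_id = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  i <- which(abs(truth$concentrations - concentration) < 1e-9)
  if (!length(i))
    .stopf("concentration %g M is not on the truth grid", concentration)
  i <- i[1L]
  .with_seed(vial_seed, {
    n_surv <- stats::rbinom(1L, truth$n_embryos, truth$viability[i])
    events <- if (n_surv > 0L)
      sample_pupariation_times(n_surv, truth$s_dvp[i], truth$lambda[i])
    else numeric(0)
    end <- if (n_surv > 0L) max(events) + 24 else 24
    grid <- seq(0, by = truth$obs_interval_h,
                length.out = ceiling(end / truth$obs_interval_h) + 1L)
    cum <- vapply(grid, function(g) sum(events <= g), integer(1))
    vial_series(
      vial_id = vial_id %||% sprintf("E%.2f_s%d", concentration, vial_seed),
      concentration = concentration,
      n_embryos = truth$n_embryos,
      times = grid, cum_counts = cum)
  })
}

#' Generate a full synthetic experiment
#'
#' Simulates `n_vials` vials at every grid concentration. Per-vial seeds are
#' derived from the truth's root seed by concentration and vial index, so
#' any subset of vials is reproducible on its own. Optionally writes the
#' counts CSV and a ground-truth JSON sidecar.
#'
#' @param truth A [build_truth()] object.
#' @param csv_path Optional path for the counts CSV.
#' @param truth_path Optional path for the truth JSON.
#'
#' @return List with `vials` (list of [vial_series]) and `truth`.
#' @export
generate_experiment <- function(truth, csv_path = NULL, truth_path = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  vials <- list()
  for (i in seq_along(truth$concentrations)) {
    for (j in seq_len(truth$n_vials)) {
      vs <- .vial_seed(truth$seed, i, j)
      vials[[length(vials) + 1L]] <- simulate_vial(
        truth$concentrations[i], truth, vial_seed = vs,
        vial_id = sprintf("E%.2f_v%d", truth$concentrations[i], j))
    }
  }
  if (!is.null(csv_path)) write_counts_csv(vials, csv_path)
  if (!is.null(truth_path)) {
    sidecar <- list(
      s_dvp_norm = unclass(truth$s_dvp_norm),
      tmid_norm = unclass(truth$tmid_norm),
      concentrations = truth$concentrations,
      viability = truth$viability,
      n_vials = truth$n_vials, n_embryos = truth$n_embryos,
      obs_interval_h = truth$obs_interval_h, seed = truth$seed)
    jsonlite::write_json(sidecar, truth_path, auto_unbox = TRUE, digits = NA)
  }
  list(vials = vials, truth = truth)
}

.vial_seed <- function(root, conc_index, vial_index) {
  as.integer((as.numeric(root) + 10007 * conc_index + 101 * vial_index) %%
               2147483647)
}

#' Thin a vial's observation schedule
#'
#' Keeps only the observations whose clock time matches the requested daily
#' schedule: with time 0 at 9 a.m., three observations per day keeps the
#' full 8 h grid (offsets 0, 8, 16 h), twice daily keeps 9 a.m. and 5 p.m.
#' (offsets 0, 8), and once daily keeps 9 a.m. only (offset 0). Retained
#' cumulative counts are unchanged; thinning only removes observation
#' times.
#'
#' @param series A [vial_series] on an 8 h grid aligned to time 0.
#' @param per_day 1, 2, or 3 observations per day.
#' @param clock_offsets_h Optional explicit offsets (hours mod 24)
#'   overriding the `per_day` mapping; must lie on the 8 h grid.
#'
#' @return A [vial_series] with the thinned schedule.
#' @export
downsample_schedule <- function(series, per_day = 3L, clock_offsets_h = NULL) {
  stopifnot(inherits(series, "vial_series"))
  if (is.null(clock_offsets_h)) {
    clock_offsets_h <- switch(as.character(per_day),
                              "3" = c(0, 8, 16),
                              "2" = c(0, 8),
                              "1" = 0,
                              .stopf("per_day must be 1, 2, or 3"))
  }
  if (any(clock_offsets_h %% 8 != 0) || any(clock_offsets_h < 0) ||
      any(clock_offsets_h >= 24))
    .stopf("clock offsets must be on the 8 h grid within one day (0, 8, 16)")
  if (any(series$times %% 8 != 0))
    .stopf("series is not on an 8 h grid aligned to time 0")
  keep <- (series$times %% 24) %in% clock_offsets_h
  if (!any(keep)) .stopf("schedule retains no observations")
  vial_series(series$vial_id, series$concentration, series$n_embryos,
              series$times[keep], series$cum_counts[keep],
              response = series$response)
}
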