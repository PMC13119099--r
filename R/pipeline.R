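# Orchestration: primary parameter tables, secondary reaction-norm results,
# sampling-frequency comparisons, and reproduction of the packaged reference
# parameter tables.

.PRIMARY_MODELS <- c("gompertz", "dose_response", "logit")

.fit_one_model <- function(model, curve) {
  switch(model,
         gompertz = fit_gompertz(curve),
         dose_response = {
           if (any(curve$times <= 0)) {
             # t = 0 carries no information for a curve on a log-time axis
             # (the response there is structurally 0); drop it rather than
             # refuse the whole treatment
             keep <- curve$times > 0
             curve <- normalized_curve(curve$concentration,
                                       curve$times[keep], curve$y[keep])
           }
           fit_dose_response(curve)
         },
         logit = fit_logit_linear(logit_transform(curve)),
         .stopf("unknown model '%s'", model))
}

#' Fit primary models across all concentrations
#'
#' Aggregates replicates, normalizes each treatment curve, and fits the
#' selected primary models, returning one row per model and concentration.
#' Treatments whose fit fails (no survivors, degenerate curve,
#' non-convergence) are reported as rows with missing parameters and the
#' failure reason rather than dropped silently.
#'
#' @param vials List of [vial_series].
#' @param models Subset of `c("gompertz", "dose_response", "logit")`.
#'
#' @return Data frame with columns `model`, `concentration_M`, `s_dvp`,
#'   `t_mid`, `lambda`, `sse`, `r2`, `nrmse`, `n_points`, `status`.
#' @export
run_primary_table <- function(vials, models = .PRIMARY_MODELS) {
  models <- match.arg(models, .PRIMARY_MODELS, several.ok = TRUE)
  concs <- sort(unique(vapply(vials, function(v) v$concentration, numeric(1))))
  rows <- list()
  n_ok <- 0L
  for (conc in concs) {
    curve <- tryCatch(normalize_curve(aggregate_replicates(vials, conc)),
                      error = function(e) e)
    for (model in models) {
      if (inherits(curve, "error")) {
        fit <- curve
      } else {
        fit <- tryCatch(.fit_one_model(model, curve), error = function(e) e)
      }
      if (inherits(fit, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          model = model, concentration_M = conc, s_dvp = NA_real_,
          t_mid = NA_real_, lambda = NA_real_, sse = NA_real_, r2 = NA_real_,
          nrmse = NA_real_, n_points = NA_integer_,
          status = conditionMessage(fit), stringsAsFactors = FALSE)
      } else {
        n_ok <- n_ok + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          model = model, concentration_M = conc, s_dvp = fit$s_dvp,
          t_mid = fit$t_mid, lambda = fit$lambda, sse = fit$sse, r2 = fit$r2,
          nrmse = fit$nrmse, n_points = fit$n_points, status = "ok",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (n_ok == 0L)
    .stopf("no concentration produced a fittable curve")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a primary parameter table to CSV
#'
#' @param param_table Output of [run_primary_table()].
#' @param path Output path.
#'
#' @return `path`, invisibly.
#' @export
write_parameter_csv <- function(param_table, path) {
  num <- vapply(param_table, is.numeric, logical(1))
  param_table[num] <- lapply(param_table[num], .signif6)
  utils::write.csv(param_table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Fit secondary reaction norms for every model and parameter
#'
#' For each primary model present in the parameter table and each requested
#' parameter, regresses the parameter on concentration with both the linear
#' and the bilinear model, compares them by AIC, and (optionally) attaches
#' residual-bootstrap confidence intervals for the bilinear coefficients.
#'
#' @param param_table Data frame as from [run_primary_table()] (columns
#'   `model`, `concentration_M`, `s_dvp`, `t_mid`).
#' @param parameters Which parameters to model (default both).
#' @param n_boot Bootstrap resamples (default 1000); set to 0 to skip the
#'   bootstrap.
#' @param seed Root seed for the bootstrap.
#'
#' @return An object of class `secondary_results`: a list with one entry
#'   per model x parameter (each holding `linear`, `bilinear`, `delta_aic`,
#'   `bootstrap`), plus `summary` (a data frame) and provenance (`seed`,
#'   `input_hash`).
#' @export
run_secondary_table <- function(param_table, parameters = c("s_dvp", "t_mid"),
                                n_boot = 1000L, seed = 1L) {
  parameters <- match.arg(parameters, c("s_dvp", "t_mid"), several.ok = TRUE)
  stopifnot(length(parameters) >= 1L)
  input_hash <- .object_hash(param_table)
  results <- list()
  summary_rows <- list()
  for (model in unique(param_table$model)) {
    sub <- param_table[param_table$model == model, , drop = FALSE]
    if ("status" %in% names(sub)) sub <- sub[sub$status == "ok", , drop = FALSE]
    for (param in parameters) {
      x <- sub$concentration_M
      y <- sub[[param]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 5L)
        .stopf("fewer than 5 usable concentrations for %s / %s", model, param)
      cmp <- compare_linear_bilinear(x[ok], y[ok], parameter = param)
      boot <- if (n_boot >= 1L)
        residual_bootstrap_bilinear(x[ok], y[ok], n_boot = n_boot,
                                    seed = seed, parameter = param)
      else NULL
      key <- paste(model, param, sep = ".")
      results[[key]] <- list(model = model, parameter = param,
                             linear = cmp$linear, bilinear = cmp$bilinear,
                             delta_aic = cmp$delta_aic, bootstrap = boot)
      summary_rows[[key]] <- data.frame(
        model = model, parameter = param,
        x_c = cmp$bilinear$x_c,
        a1 = cmp$bilinear$coef[["a1"]], b1 = cmp$bilinear$coef[["b1"]],
        a2 = cmp$bilinear$coef[["a2"]], b2 = cmp$bilinear$coef[["b2"]],
        aic_linear = cmp$linear$aic, aic_bilinear = cmp$bilinear$aic,
        delta_aic = cmp$delta_aic,
        r2_bilinear = cmp$bilinear$r2, nrmse_bilinear = cmp$bilinear$nrmse,
        x_c_lower = if (!is.null(boot)) boot$ci$lower[boot$ci$statistic == "x_c"] else NA_real_,
        x_c_upper = if (!is.null(boot)) boot$ci$upper[boot$ci$statistic == "x_c"] else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  structure(
    list(results = results,
         summary = do.call(rbind, c(summary_rows, make.row.names = FALSE)),
         seed = as.integer(seed), n_boot = as.integer(n_boot),
         input_hash = input_hash),
    class = "secondary_results")
}

#' @export
print.secondary_results <- function(x, ...) {
  cat(sprintf("<secondary_results> %d model x parameter fits, n_boot=%d, seed=%d, input %s\n",
              length(x$results), x$n_boot, x$seed, x$input_hash))
  df <- x$summary
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, 4)
  print(df)
  invisible(x)
}

#' Write secondary results as JSON
#'
#' Serializes the per-(model, parameter) fits, the AIC comparison, the
#' bootstrap intervals, and the provenance fields (input hash, seeds) with
#' numbers formatted at 6 significant digits, so identical configurations
#' give byte-identical files.
#'
#' @param results A `secondary_results` object.
#' @param path Output path.
#'
#' @return `path`, invisibly.
#' @export
write_secondary_json <- function(results, path) {
  stopifnot(inherits(results, "secondary_results"))
  blocks <- lapply(results$results, function(r) {
    out <- list(
      model = r$model, parameter = r$parameter,
      linear = list(a = .signif6(r$linear$coef[["a"]]),
                    b = .signif6(r$linear$coef[["b"]]),
                    sse = .signif6(r$linear$sse),
                    aic = .signif6(r$linear$aic)),
      bilinear = list(a1 = .signif6(r$bilinear$coef[["a1"]]),
                      b1 = .signif6(r$bilinear$coef[["b1"]]),
                      a2 = .signif6(r$bilinear$coef[["a2"]]),
                      b2 = .signif6(r$bilinear$coef[["b2"]]),
                      x_c = .signif6(r$bilinear$x_c),
                      fallback = r$bilinear$fallback,
                      sse = .signif6(r$bilinear$sse),
                      aic = .signif6(r$bilinear$aic)),
      delta_aic = .signif6(r$delta_aic),
      r2 = .signif6(r$bilinear$r2),
      nrmse = .signif6(r$bilinear$nrmse))
    if (!is.null(r$bootstrap)) {
      ci <- r$bootstrap$ci
      out$bootstrap <- c(
        stats::setNames(lapply(seq_len(nrow(ci)), function(i)
          list(point = .signif6(ci$point[i]), lower = .signif6(ci$lower[i]),
               upper = .signif6(ci$upper[i]))), ci$statistic),
        list(n_boot = r$bootstrap$n_boot, seed = r$bootstrap$seed,
             n_fallback = r$bootstrap$n_fallback,
             n_failed = r$bootstrap$n_failed))
    }
    out
  })
  payload <- list(results = blocks, seed = results$seed,
                  n_boot = results$n_boot, input_hash = results$input_hash)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Compare observation schedules
#'
#' Thins every vial to each requested daily schedule, refits the Gompertz
#' primary model per concentration, refits the bilinear reaction norms, and
#' reports breakpoint and fit quality per schedule and parameter: the
#' sampling-frequency robustness analysis.
#'
#' @param vials List of [vial_series] on the full 8 h grid.
#' @param schedules Observations per day to compare (subset of 3, 2, 1).
#'
#' @return Data frame with columns `per_day`, `parameter`, `x_c`,
#'   `r2`, `nrmse`, `n_fits`, `fallback`.
#' @export
sampling_frequency_experiment <- function(vials, schedules = c(3L, 2L, 1L)) {
  stopifnot(all(schedules %in% c(1L, 2L, 3L)))
  rows <- list()
  for (per_day in schedules) {
    thinned <- lapply(vials, downsample_schedule, per_day = per_day)
    ptab <- run_primary_table(thinned, models = "gompertz")
    ok <- ptab[ptab$status == "ok", , drop = FALSE]
    n_bad <- nrow(ptab) - nrow(ok)
    if (n_bad > 0L)
      .warnf("%d of %d Gompertz fits failed or were degenerate at %d obs/day",
             n_bad, nrow(ptab), per_day)
    for (param in c("s_dvp", "t_mid")) {
      bil <- fit_bilinear(ok$concentration_M, ok[[param]], parameter = param)
      rows[[length(rows) + 1L]] <- data.frame(
        per_day = per_day, parameter = param, x_c = bil$x_c, r2 = bil$r2,
        nrmse = bil$nrmse, n_fits = nrow(ok), fallback = bil$fallback,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Packaged reference parameter tables
#'
#' Published per-concentration `t_mid` and `s_dvp` estimates for the three
#' primary models over the 0-1.5 M sucrose grid, shipped as plain-text
#' fixtures. These are the inputs on which the secondary modeling results
#' can be reproduced without access to the raw vial counts.
#'
#' @param parameter `"t_mid"`, `"s_dvp"`, or `"both"` (default) to merge.
#'
#' @return Data frame with columns `model`, `concentration_M`, and the
#'   requested parameter column(s).
#' @export
reference_parameter_table <- function(parameter = c("both", "t_mid", "s_dvp")) {
  parameter <- match.arg(parameter)
  read_fix <- function(fname, col) {
    path <- system.file("extdata", fname, package = "devkin", mustWork = TRUE)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    names(df)[names(df) == "value"] <- col
    df
  }
  tmid <- read_fix("table1_tmid.csv", "t_mid")
  sdvp <- read_fix("table2_sdvp.csv", "s_dvp")
  switch(parameter,
         t_mid = tmid,
         s_dvp = sdvp,
         both = merge(sdvp, tmid, by = c("model", "concentration_M"),
                      sort = FALSE))
}

#' Reproduce the secondary modeling results from the packaged tables
#'
#' Runs the full secondary pipeline (linear and bilinear reaction norms, AIC
#' comparison, residual bootstrap) on the packaged reference parameter
#' tables: the from-fixtures reproduction of the published breakpoint
#' analysis.
#'
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Root seed for the bootstrap.
#'
#' @return A `secondary_results` object.
#' @export
reproduce_reference_tables <- function(n_boot = 1000L, seed = 1L) {
  tab <- reference_parameter_table("both")
  run_secondary_table(tab, parameters = c("s_dvp", "t_mid"),
                      n_boot = n_boot, seed = seed)
}

#' Pipeline configuration
#'
#' Validated bag of options for [run_pipeline()].
#'
#' @param models Primary models to fit.
#' @param parameters Secondary parameters to model.
#' @param n_boot Bootstrap resamples (>= 100 when CIs are reported, or 0 to
#'   skip).
#' @param seed Root seed.
#' @param schedules Sampling schedules (observations/day) to compare; NULL
#'   to skip the frequency analysis.
#' @param alpha Significance level for viability statistics.
#'
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(models = .PRIMARY_MODELS,
                            parameters = c("s_dvp", "t_mid"),
                            n_boot = 1000L, seed = 1L,
                            schedules = c(3L, 2L, 1L), alpha = 0.05) {
  models <- match.arg(models, .PRIMARY_MODELS, several.ok = TRUE)
  parameters <- match.arg(parameters, c("s_dvp", "t_mid"), several.ok = TRUE)
  if (length(models) < 1L || length(parameters) < 1L)
    .stopf("select at least one model and one parameter")
  if (n_boot != 0L && n_boot < 100L)
    .stopf("n_boot must be 0 (skip) or >= 100 for interval reporting")
  structure(list(models = models, parameters = parameters,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 schedules = schedules, alpha = alpha),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments.
#'
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    .stopf("the 'yaml' package is required to read YAML configurations")
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg[intersect(names(cfg),
                                         names(formals(pipeline_config)))])
}

#' Run the full analysis pipeline
#'
#' Primary fits, secondary reaction norms with bootstrap, the
#' sampling-frequency comparison, and viability statistics, with all
#' outputs written under `out_dir` (`params.csv`, `secondary.json`,
#' `frequency.csv`, `viability.json`).
#'
#' @param vials List of [vial_series], or a path to a counts CSV.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing); NULL to skip
#'   writing.
#'
#' @return List with `primary`, `secondary`, `frequency`, `viability`.
#' @export
run_pipeline <- function(vials, config = pipeline_config(), out_dir = NULL) {
  if (is.character(vials)) vials <- read_counts_csv(vials)
  primary <- run_primary_table(vials, config$models)
  secondary <- run_secondary_table(primary, config$parameters,
                                   n_boot = config$n_boot, seed = config$seed)
  frequency <- if (!is.null(config$schedules))
    sampling_frequency_experiment(vials, config$schedules)
  else NULL
  viability <- viability_stats(vials, alpha = config$alpha)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_parameter_csv(primary, file.path(out_dir, "params.csv"))
    write_secondary_json(secondary, file.path(out_dir, "secondary.json"))
    if (!is.null(frequency)) {
      freq <- frequency
      num <- vapply(freq, is.numeric, logical(1))
      freq[num] <- lapply(freq[num], .signif6)
      utils::write.csv(freq, file.path(out_dir, "frequency.csv"),
                       row.names = FALSE, fileEncoding = "UTF-8")
    }
    jsonlite::write_json(
      list(anova = lapply(viability$anova, .signif6),
           levene = lapply(viability$levene, .signif6),
           moments = lapply(viability$moments, .signif6),
           letters = as.list(viability$tukey$letters)),
      file.path(out_dir, "viability.json"), auto_unbox = TRUE, digits = NA)
  }
  list(primary = primary, secondary = secondary, frequency = frequency,
       viability = viability)
}
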