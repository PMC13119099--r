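#' Vial-level cumulative count series
#'
#' Container for one vial's cumulative pupariation (or eclosion) counts over
#' time, together with the design metadata needed downstream: the sucrose
#' concentration of the rearing medium and the number of embryos seeded.
#' Times are hours since the midpoint of the 2 h embryo-collection window.
#'
#' @param vial_id Character scalar identifying the vial.
#' @param concentration Sucrose molarity of the medium (mol/L, >= 0).
#' @param n_embryos Number of embryos seeded (positive integer).
#' @param times Observation times in hours, strictly increasing.
#' @param cum_counts Cumulative counts at each time; non-decreasing integers
#'   in `[0, n_embryos]`.
#' @param response Which developmental event the counts record, `"pupae"` or
#'   `"adults"`.
#'
#' @return An object of class `vial_series`.
#' @export
vial_series <- function(vial_id, concentration, n_embryos, times, cum_counts,
                        response = c("pupae", "adults")) {
  response <- match.arg(response)
  vial_id <- as.character(vial_id)
  if (length(vial_id) != 1L || is.na(vial_id) || !nzchar(vial_id))
    .stopf("vial_id must be a non-empty string")
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      !is.finite(concentration) || concentration < 0)
    .stopf("concentration must be a single non-negative number (mol/L)")
  if (!.is_count(n_embryos) || length(n_embryos) != 1L || n_embryos <= 0)
    .stopf("n_embryos must be a single positive integer")
  if (length(times) != length(cum_counts))
    .stopf("times and cum_counts must have equal length")
  if (length(times) < 1L) .stopf("vial '%s' has no observations", vial_id)
  if (!is.numeric(times) || any(!is.finite(times)))
    .stopf("times must be finite numbers")
  if (any(diff(times) <= 0))
    .stopf("times must be strictly increasing in vial '%s'", vial_id)
  if (!.is_count(cum_counts))
    .stopf("cum_counts must be non-negative integers in vial '%s'", vial_id)
  bad <- which(diff(cum_counts) < 0)
  if (length(bad))
    .stopf("cumulative count decreases in vial '%s' at time %g h",
           vial_id, times[bad[1L] + 1L])
  if (any(cum_counts < 0) || any(cum_counts > n_embryos))
    .stopf("cum_counts must lie in [0, n_embryos] in vial '%s'", vial_id)
  structure(
    list(vial_id = vial_id, concentration = concentration,
         n_embryos = as.integer(n_embryos), times = as.numeric(times),
         cum_counts = as.integer(cum_counts), response = response),
    class = "vial_series")
}

#' @export
print.vial_series <- function(x, ...) {
  cat(sprintf("<vial_series> %s  %.2f M  %d embryos  %d obs (%g-%g h)  final %d %s\n",
              x$vial_id, x$concentration, x$n_embryos, length(x$times),
              min(x$times), max(x$times), x$cum_counts[length(x$cum_counts)],
              x$response))
  invisible(x)
}

#' Replicate-averaged treatment curve
#'
#' One cumulative developmental curve per sucrose concentration, obtained by
#' averaging replicate vials. `viability` is the fraction of seeded embryos
#' that reached the recorded stage by the end of the experiment.
#'
#' @param concentration Sucrose molarity (mol/L).
#' @param times Observation times (hours).
#' @param mean_counts Replicate-averaged cumulative counts (non-decreasing).
#' @param n_replicates Number of vials averaged.
#' @param viability Fraction in `[0, 1]`.
#'
#' @return An object of class `treatment_curve`.
#' @export
treatment_curve <- function(concentration, times, mean_counts, n_replicates,
                            viability) {
  if (length(times) != length(mean_counts))
    .stopf("times and mean_counts must have equal length")
  if (any(diff(times) <= 0)) .stopf("times must be strictly increasing")
  if (any(mean_counts < 0)) .stopf("mean_counts must be non-negative")
  if (any(diff(mean_counts) < -1e-9))
    .stopf("mean_counts must be non-decreasing")
  if (viability < 0 || viability > 1)
    .stopf("viability must lie in [0, 1], got %g", viability)
  structure(
    list(concentration = concentration, times = as.numeric(times),
         mean_counts = as.numeric(mean_counts),
         n_replicates = as.integer(n_replicates),
         y_max_count = mean_counts[length(mean_counts)],
         viability = viability),
    class = "treatment_curve")
}

#' @export
print.treatment_curve <- function(x, ...) {
  cat(sprintf("<treatment_curve> %.2f M  %d replicates  %d obs  y_max %.2f  viability %.3f\n",
              x$concentration, x$n_replicates, length(x$times), x$y_max_count,
              x$viability))
  invisible(x)
}

#' Normalized developmental curve
#'
#' A treatment curve rescaled by its final value so the response runs from 0
#' to exactly 1; this is the input all primary model fits operate on.
#'
#' @param concentration Sucrose molarity (mol/L).
#' @param times Observation times (hours).
#' @param y Normalized response, non-decreasing, last element exactly 1.
#'
#' @return An object of class `normalized_curve`.
#' @export
normalized_curve <- function(concentration, times, y) {
  if (length(times) != length(y)) .stopf("times and y must have equal length")
  if (any(diff(times) <= 0)) .stopf("times must be strictly increasing")
  if (y[1L] < 0) .stopf("normalized response must be non-negative")
  if (any(diff(y) < -1e-12)) .stopf("normalized response must be non-decreasing")
  if (abs(y[length(y)] - 1) > 1e-12)
    .stopf("normalized response must end at exactly 1")
  y[length(y)] <- 1
  structure(list(concentration = concentration, times = as.numeric(times),
                 y = as.numeric(y)),
            class = "normalized_curve")
}

#' @export
print.normalized_curve <- function(x, ...) {
  cat(sprintf("<normalized_curve> %.2f M  %d points (%g-%g h)\n",
              x$concentration, length(x$times), min(x$times), max(x$times)))
  invisible(x)
}

#' Read vial count data from a long-format CSV
#'
#' Expected columns: `vial_id`, `concentration_M`, `n_embryos`, `time_h`,
#' `cum_pupae`, and optionally `cum_adults`. One [vial_series] is produced
#' per vial and response type, with rows sorted by time within each vial.
#'
#' @param path Path to a CSV file (comma separator, decimal point, UTF-8).
#'
#' @return A list of [vial_series] objects.
#' @export
read_counts_csv <- function(path) {
  if (!file.exists(path)) .stopf("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- c("vial_id", "concentration_M", "n_embryos", "time_h", "cum_pupae")
  missing <- setdiff(required, names(df))
  if (length(missing))
    .stopf("count CSV is missing required column(s): %s",
           paste(missing, collapse = ", "))
  responses <- c(cum_pupae = "pupae")
  if ("cum_adults" %in% names(df)) responses <- c(responses, cum_adults = "adults")
  out <- list()
  for (id in unique(df$vial_id)) {
    rows <- df[df$vial_id == id, , drop = FALSE]
    rows <- rows[order(rows$time_h), , drop = FALSE]
    for (col in names(responses)) {
      cnt <- rows[[col]]
      if (all(is.na(cnt))) next
      out[[length(out) + 1L]] <- vial_series(
        vial_id = id,
        concentration = rows$concentration_M[1L],
        n_embryos = rows$n_embryos[1L],
        times = rows$time_h,
        cum_counts = cnt,
        response = responses[[col]])
    }
  }
  out
}

#' Write vial count data to a long-format CSV
#'
#' Inverse of [read_counts_csv()]: the round trip preserves all fields
#' exactly for integer counts.
#'
#' @param vials A list of [vial_series] objects.
#' @param path Output CSV path.
#'
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(vials, path) {
  stopifnot(length(vials) > 0)
  pup <- Filter(function(v) v$response == "pupae", vials)
  adu <- Filter(function(v) v$response == "adults", vials)
  rows <- do.call(rbind, lapply(pup, function(v) {
    data.frame(vial_id = v$vial_id, concentration_M = v$concentration,
               n_embryos = v$n_embryos, time_h = v$times,
               cum_pupae = v$cum_counts, stringsAsFactors = FALSE)
  }))
  if (length(adu)) {
    arows <- do.call(rbind, lapply(adu, function(v) {
      data.frame(vial_id = v$vial_id, time_h = v$times,
                 cum_adults = v$cum_counts, stringsAsFactors = FALSE)
    }))
    rows <- merge(rows, arows, by = c("vial_id", "time_h"), all.x = TRUE,
                  sort = FALSE)
    rows <- rows[order(match(rows$vial_id, unique(rows$vial_id)), rows$time_h), ]
  }
  utils::write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Average replicate vials at one concentration
#'
#' Builds the single growth curve per treatment on which primary fitting is
#' done: the arithmetic mean of the replicate vials' cumulative counts at
#' each observation time. When replicate vials were observed on different
#' grids, the union of times is used and each vial's last observed cumulative
#' count is carried forward (cumulative counts are step functions, so this
#' needs no interpolation assumption). Viability is the mean over vials of
#' (final count / embryos seeded in that vial).
#'
#' @param vials A list of [vial_series] objects.
#' @param concentration Concentration (mol/L) selecting the replicates.
#'
#' @return A [treatment_curve].
#' @export
aggregate_replicates <- function(vials, concentration) {
  sel <- Filter(function(v) isTRUE(abs(v$concentration - concentration) < 1e-9),
                vials)
  if (!length(sel))
    .stopf("no vials at concentration %g M", concentration)
  ns <- vapply(sel, function(v) v$n_embryos, integer(1))
  if (length(unique(ns)) > 1L)
    .warnf("inconsistent n_embryos across vials at %g M; using per-vial n in viability",
           concentration)
  grid <- sort(unique(unlist(lapply(sel, function(v) v$times))))
  counts <- vapply(sel, function(v) {
    # last observation carried forward; 0 before the first observation
    idx <- findInterval(grid, v$times)
    c(0L, v$cum_counts)[idx + 1L]
  }, numeric(length(grid)))
  counts <- matrix(counts, nrow = length(grid))
  finals <- vapply(sel, function(v) v$cum_counts[length(v$cum_counts)],
                   integer(1))
  treatment_curve(
    concentration = sel[[1L]]$concentration,
    times = grid,
    mean_counts = rowMeans(counts),
    n_replicates = length(sel),
    viability = mean(finals / ns))
}

#' Normalize a treatment curve to its final value
#'
#' Rescales the replicate-averaged cumulative counts by the final count so
#' the curve ends at exactly 1, the form the primary sigmoid models are
#' fitted to.
#'
#' @param curve A [treatment_curve].
#'
#' @return A [normalized_curve].
#' @export
normalize_curve <- function(curve) {
  stopifnot(inherits(curve, "treatment_curve"))
  if (curve$y_max_count <= 0)
    .stopf("empty curve: no survivors at concentration %g M",
           curve$concentration)
  normalized_curve(curve$concentration, curve$times,
                   curve$mean_counts / curve$y_max_count)
}
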