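# Replicate-level viability analysis: one-way ANOVA with eta-squared, Tukey
# HSD with a compact letter display, mean-centered Levene's test, and
# residual moment diagnostics.

.check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    .stopf("need at least 2 groups")
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 2L))
    .stopf("every group needs at least 2 values (group %s has %d)",
           names(groups)[which(sizes < 2L)[1L]] %||% which(sizes < 2L)[1L],
           min(sizes))
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  groups
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.groups_to_df <- function(groups) {
  data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), vapply(groups, length, integer(1))),
                   levels = names(groups)))
}

#' One-way ANOVA with eta-squared effect size
#'
#' Classical fixed-effects one-way ANOVA across groups of replicate
#' viabilities, with the effect size `eta2 = SS_between / SS_total`.
#'
#' @param groups Named list of numeric vectors, one per concentration group,
#'   each with at least 2 values.
#'
#' @return Named list with `F`, `p`, `eta2`, `df_between`, `df_within`, and
#'   the `residuals` of the group-mean model.
#' @export
one_way_anova_eta2 <- function(groups) {
  groups <- .check_groups(groups)
  df <- .groups_to_df(groups)
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1L]]
  ssb <- tab[["Sum Sq"]][1L]
  ssw <- tab[["Sum Sq"]][2L]
  list(F = tab[["F value"]][1L],
       p = tab[["Pr(>F)"]][1L],
       eta2 = ssb / (ssb + ssw),
       df_between = tab[["Df"]][1L],
       df_within = tab[["Df"]][2L],
       residuals = unname(stats::residuals(fit)))
}

# Greedy insert-and-absorb compact letter display from the adjacency of
# non-significant pairs. Presentation aid only; the adjusted p-values carry
# the inference.
.compact_letters <- function(group_names, ns_pairs) {
  k <- length(group_names)
  same <- diag(TRUE, k)
  dimnames(same) <- list(group_names, group_names)
  for (i in seq_len(nrow(ns_pairs))) {
    same[ns_pairs[i, 1L], ns_pairs[i, 2L]] <- TRUE
    same[ns_pairs[i, 2L], ns_pairs[i, 1L]] <- TRUE
  }
  sets <- list()
  for (g in group_names) {
    placed <- FALSE
    for (j in seq_along(sets)) {
      if (all(same[g, sets[[j]]])) {
        sets[[j]] <- c(sets[[j]], g)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1L]] <- g
  }
  # absorb sets fully contained in another
  keep <- rep(TRUE, length(sets))
  for (j in seq_along(sets)) {
    for (l in seq_along(sets)) {
      if (j != l && keep[l] && all(sets[[j]] %in% sets[[l]]) &&
          length(sets[[j]]) < length(sets[[l]]))
        keep[j] <- FALSE
    }
  }
  sets <- sets[keep]
  letters_out <- stats::setNames(rep("", k), group_names)
  for (j in seq_along(sets)) {
    for (g in sets[[j]])
      letters_out[g] <- paste0(letters_out[g], letters[j])
  }
  letters_out
}

#' Tukey HSD pairwise comparisons with letter display
#'
#' Studentized-range adjusted pairwise comparisons following a one-way
#' ANOVA, plus a compact letter display: groups sharing a letter are not
#' significantly different at `alpha`.
#'
#' @param groups Named list of numeric vectors (>= 2 each).
#' @param alpha Significance level for the letter display (default 0.05).
#'
#' @return List with `pairs` (data.frame: `group1`, `group2`, `diff`,
#'   `lwr`, `upr`, `p_adj`) and `letters` (named character vector).
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  groups <- .check_groups(groups)
  df <- .groups_to_df(groups)
  fit <- stats::aov(value ~ group, data = df)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  ids <- strsplit(rownames(tk), "-", fixed = TRUE)
  pairs <- data.frame(
    group1 = vapply(ids, `[`, character(1), 1L),
    group2 = vapply(ids, `[`, character(1), 2L),
    diff = unname(tk[, "diff"]),
    lwr = unname(tk[, "lwr"]),
    upr = unname(tk[, "upr"]),
    p_adj = unname(tk[, "p adj"]),
    stringsAsFactors = FALSE)
  ns <- pairs[pairs$p_adj >= alpha, c("group1", "group2"), drop = FALSE]
  list(pairs = pairs,
       letters = .compact_letters(names(groups), as.matrix(ns)))
}

#' Levene's test for homogeneity of variances (mean-centered)
#'
#' One-way ANOVA applied to the absolute deviations of each value from its
#' group mean (Levene's original, mean-centered form).
#'
#' @param groups Named list of numeric vectors (>= 2 each).
#'
#' @return Named list with the statistic `W` and p-value `p`.
#' @export
levene_mean_centered <- function(groups) {
  groups <- .check_groups(groups)
  absdev <- lapply(groups, function(g) abs(g - mean(g)))
  a <- one_way_anova_eta2(absdev)
  list(W = a$F, p = a$p)
}

#' Sample-corrected skewness and excess kurtosis
#'
#' Adjusted Fisher-Pearson moment estimators (the convention used by
#' spreadsheet SKEW/KURT functions): skewness
#' `n / ((n-1)(n-2)) * sum(z^3)` and excess kurtosis
#' `n(n+1) / ((n-1)(n-2)(n-3)) * sum(z^4) - 3 (n-1)^2 / ((n-2)(n-3))`,
#' with `z` standardized by the sample (n-1) standard deviation.
#'
#' @param residuals Numeric vector, length >= 4, non-zero variance.
#'
#' @return Named list with `skewness` and `excess_kurtosis`.
#' @export
residual_moments <- function(residuals) {
  n <- length(residuals)
  if (n < 4L) .stopf("need at least 4 values, got %d", n)
  s <- stats::sd(residuals)
  if (s == 0) .stopf("residuals have zero variance")
  z <- (residuals - mean(residuals)) / s
  skew <- n / ((n - 1) * (n - 2)) * sum(z^3)
  kurt <- n * (n + 1) / ((n - 1) * (n - 2) * (n - 3)) * sum(z^4) -
    3 * (n - 1)^2 / ((n - 2) * (n - 3))
  list(skewness = skew, excess_kurtosis = kurt)
}

#' Full viability analysis of a vial collection
#'
#' Groups per-vial viabilities (final cumulative count / embryos seeded) by
#' concentration and runs the one-way ANOVA with eta-squared, Tukey HSD with
#' letters, the mean-centered Levene test, and residual moment diagnostics.
#'
#' @param vials List of [vial_series].
#' @param alpha Significance level for the Tukey letters (default 0.05).
#'
#' @return List with `anova`, `tukey`, `levene`, `moments`, and the
#'   `viabilities` grouping used.
#' @export
viability_stats <- function(vials, alpha = 0.05) {
  conc <- vapply(vials, function(v) v$concentration, numeric(1))
  viab <- vapply(vials, function(v)
    v$cum_counts[length(v$cum_counts)] / v$n_embryos, numeric(1))
  groups <- split(viab, format(conc, trim = TRUE))
  groups <- groups[order(as.numeric(names(groups)))]
  an <- one_way_anova_eta2(groups)
  list(anova = an[c("F", "p", "eta2", "df_between", "df_within")],
       tukey = tukey_hsd(groups, alpha),
       levene = levene_mean_centered(groups),
       moments = residual_moments(an$residuals),
       viabilities = groups)
}
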