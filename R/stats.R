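# Statistical battery for morphometric tables: Levene-routed group
# comparison (ANOVA + Tukey for homoscedastic data, Kruskal-Wallis + Dunn
# with Benjamini-Hochberg correction otherwise) with compact letter
# displays, Spearman trend tests, an absolute-deviation variability test,
# and regression slopes with 95% confidence intervals.

#' Compare a metric across groups with variance routing
#'
#' Equality of variances is checked with the classic (mean-centered) Levene
#' test; when its p-value is at least `levene_alpha` the data are treated
#' as parametric and analysed by one-way ANOVA with Tukey honest
#' significant difference post hoc grouping, otherwise by a Kruskal-Wallis
#' test with Dunn post hoc comparisons corrected by Benjamini-Hochberg.
#' Groups are then assigned compact letters (insert-and-absorb) from the
#' adjusted pairwise matrix: groups sharing a letter are not significantly
#' different at level `alpha`.
#'
#' @param values Numeric vector.
#' @param group Factor-like vector parallel to `values`; at least 2 groups
#'   of at least 2 values each.
#' @param alpha Significance level for the letter display (default 0.05).
#' @param levene_alpha Routing threshold on the Levene p-value (default
#'   0.05).
#' @return An object of class `"eq_group_comparison"`: `method`
#'   (`"anova_tukey"` or `"kruskal_dunn"`), `levene_p`, `statistic`,
#'   `p_value`, `pairwise` (adjusted p matrix), `letters` (named per
#'   group), `alpha`, `group_means`.
#' @export
compare_groups <- function(values, group, alpha = 0.05, levene_alpha = 0.05) {
  group <- factor(group)
  if (nlevels(group) < 2L) stop("need at least 2 groups")
  if (any(table(group) < 2L)) stop("every group needs at least 2 values")
  if (stats::var(values) == 0) {
    # constant data: no test can separate groups
    k <- nlevels(group)
    pmat <- matrix(1, k, k, dimnames = list(levels(group), levels(group)))
    return(structure(list(method = "degenerate", levene_p = NA_real_,
                          statistic = 0, p_value = 1, pairwise = pmat,
                          letters = cld_letters(pmat, alpha), alpha = alpha,
                          group_means = tapply(values, group, mean)),
                     class = "eq_group_comparison"))
  }
  lev <- car::leveneTest(values ~ group, center = mean)
  levene_p <- lev[["Pr(>F)"]][1]
  if (is.na(levene_p)) levene_p <- 1  # equal within-group spread (e.g. all zero)
  if (levene_p >= levene_alpha) {
    fit <- stats::aov(values ~ group)
    an <- summary(fit)[[1]]
    statistic <- an[["F value"]][1]
    p_value <- an[["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$group
    pmat <- pairwise_matrix(levels(group), rownames(tk), tk[, "p adj"])
    method <- "anova_tukey"
  } else {
    kw <- stats::kruskal.test(values, group)
    statistic <- unname(kw$statistic)
    p_value <- kw$p.value
    dn <- dunn_test(values, group, p_adjust = "BH")
    pmat <- dn$pairwise
    method <- "kruskal_dunn"
  }
  letters <- cld_letters(pmat, alpha)
  structure(list(method = method, levene_p = levene_p,
                 statistic = statistic, p_value = p_value,
                 pairwise = pmat, letters = letters, alpha = alpha,
                 group_means = tapply(values, group, mean)),
            class = "eq_group_comparison")
}

#' @export
print.eq_group_comparison <- function(x, ...) {
  cat(sprintf("<group comparison: %s (Levene p = %.3g)>\n", x$method,
              x$levene_p))
  cat(sprintf("  global statistic %.4g, p = %.3g\n", x$statistic, x$p_value))
  disp <- data.frame(mean = as.numeric(x$group_means), letters = x$letters)
  print(disp)
  invisible(x)
}

pairwise_matrix <- function(levels, pair_names, p_values) {
  k <- length(levels)
  m <- matrix(NA_real_, k, k, dimnames = list(levels, levels))
  diag(m) <- 1
  parts <- strsplit(pair_names, "-", fixed = TRUE)
  for (i in seq_along(parts)) {
    a <- parts[[i]][1]; b <- parts[[i]][2]
    m[a, b] <- m[b, a] <- p_values[i]
  }
  m
}

#' Dunn's post hoc test
#'
#' All pairwise two-sided rank comparisons following a Kruskal-Wallis test,
#' with the standard normal approximation and the usual tie correction;
#' p-values adjusted by the requested method (default Benjamini-Hochberg).
#'
#' @param values Numeric vector.
#' @param group Factor-like vector.
#' @param p_adjust Adjustment method passed to [stats::p.adjust()].
#' @return List: `pairwise` (adjusted p matrix), `z` (z-statistic matrix),
#'   `comparisons` (data.frame).
#' @export
dunn_test <- function(values, group, p_adjust = "BH") {
  group <- factor(group)
  n <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  mean_ranks <- tapply(r, group, mean)
  ns <- table(group)
  lv <- levels(group)
  k <- length(lv)
  comps <- list()
  zmat <- matrix(NA_real_, k, k, dimnames = list(lv, lv))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ns[i] + 1 / ns[j]))
    z <- (mean_ranks[i] - mean_ranks[j]) / se
    p <- 2 * stats::pnorm(-abs(z))
    zmat[i, j] <- zmat[j, i] <- z
    comps[[length(comps) + 1L]] <- data.frame(
      group1 = lv[i], group2 = lv[j], z = unname(z), p = unname(p),
      stringsAsFactors = FALSE)
  }
  comps <- do.call(rbind, comps)
  comps$p_adj <- stats::p.adjust(comps$p, method = p_adjust)
  pmat <- matrix(NA_real_, k, k, dimnames = list(lv, lv))
  diag(pmat) <- 1
  for (q in seq_len(nrow(comps))) {
    pmat[comps$group1[q], comps$group2[q]] <-
      pmat[comps$group2[q], comps$group1[q]] <- comps$p_adj[q]
  }
  list(pairwise = pmat, z = zmat, comparisons = comps)
}

#' Compact letter display from a pairwise p matrix
#'
#' Insert-and-absorb: start from one letter covering all groups; for each
#' significantly different pair sharing a letter column, split that column
#' into two (one excluding each member), then absorb columns that are
#' subsets of others. Groups share a letter iff no significant difference
#' separates them within that column.
#'
#' @param pmat Symmetric matrix of adjusted pairwise p-values with group
#'   names as dimnames.
#' @param alpha Significance level (default 0.05).
#' @return Named character vector of letter strings, one per group.
#' @export
cld_letters <- function(pmat, alpha = 0.05) {
  groups <- rownames(pmat)
  k <- length(groups)
  cols <- list(rep(TRUE, k))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (is.na(pmat[i, j]) || pmat[i, j] >= alpha) next
    new_cols <- list()
    for (col in cols) {
      if (col[i] && col[j]) {
        a <- col; a[i] <- FALSE
        b <- col; b[j] <- FALSE
        new_cols <- c(new_cols, list(a, b))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    # absorb: drop any column that is a subset of another
    keep <- rep(TRUE, length(new_cols))
    for (a_i in seq_along(new_cols)) for (b_i in seq_along(new_cols)) {
      if (a_i == b_i || !keep[a_i]) next
      if (all(!new_cols[[a_i]] | new_cols[[b_i]]) &&
          !identical(new_cols[[a_i]], new_cols[[b_i]])) {
        keep[a_i] <- FALSE
      } else if (identical(new_cols[[a_i]], new_cols[[b_i]]) && a_i > b_i) {
        keep[a_i] <- FALSE
      }
    }
    cols <- new_cols[keep]
  }
  letters_out <- rep("", k)
  for (c_i in seq_along(cols)) {
    letters_out[cols[[c_i]]] <- paste0(letters_out[cols[[c_i]]],
                                       letters[c_i])
  }
  stats::setNames(letters_out, groups)
}

#' Spearman rank correlation against an ordered covariate
#'
#' @param values Numeric vector.
#' @param ordered_time Numeric (or ordered) covariate, same length,
#'   at least 3 pairs.
#' @return Named numeric `c(rho, p)`.
#' @export
spearman_trend <- function(values, ordered_time) {
  stopifnot(length(values) >= 3L, length(values) == length(ordered_time))
  ct <- suppressWarnings(stats::cor.test(values, as.numeric(ordered_time),
                                         method = "spearman", exact = FALSE))
  c(rho = unname(ct$estimate), p = ct$p.value)
}

#' Test for differing within-group variability
#'
#' Every value is replaced by its absolute deviation from its own group
#' mean; the transformed values are then compared across groups with a
#' Kruskal-Wallis test and Dunn post hoc comparisons under
#' Benjamini-Hochberg correction, with compact letters.
#'
#' @param values Numeric vector.
#' @param group Factor-like vector.
#' @param alpha Significance level for letters (default 0.05).
#' @return An `eq_group_comparison` (method `"kruskal_dunn"` on absolute
#'   deviations) with an extra element `abs_dev` holding the transformed
#'   values.
#' @export
variability_test <- function(values, group, alpha = 0.05) {
  group <- factor(group)
  dev <- abs(values - ave(values, group))
  kw <- stats::kruskal.test(dev, group)
  dn <- dunn_test(dev, group, p_adjust = "BH")
  letters <- cld_letters(dn$pairwise, alpha)
  structure(list(method = "kruskal_dunn", levene_p = NA_real_,
                 statistic = unname(kw$statistic), p_value = kw$p.value,
                 pairwise = dn$pairwise, letters = letters, alpha = alpha,
                 group_means = tapply(dev, group, mean), abs_dev = dev),
            class = "eq_group_comparison")
}

#' Regression slope with 95% confidence interval
#'
#' Ordinary least squares of `values` on `time`; the confidence interval is
#' `slope +/- 1.96 x SE(slope)`, reading the interval half-width as 1.96
#' standard errors of the slope estimate.
#'
#' @param values Numeric response.
#' @param time Numeric covariate, at least 3 points.
#' @return Named numeric `c(slope, ci_low, ci_high, se, r_squared, p)`.
#' @export
slope_ci <- function(values, time) {
  stopifnot(length(values) >= 3L, length(values) == length(time))
  fit <- stats::lm(values ~ time)
  sm <- summary(fit)
  slope <- unname(coef(fit)[2])
  se <- sm$coefficients["time", "Std. Error"]
  if (is.na(se)) se <- 0   # exact fit: zero residual variance
  p <- sm$coefficients["time", "Pr(>|t|)"]
  c(slope = slope, ci_low = slope - 1.96 * se, ci_high = slope + 1.96 * se,
    se = se, r_squared = sm$r.squared, p = unname(p))
}

#' Full statistical report for a morphometrics table
#'
#' Runs the battery on each cell-level metric (count, density, occupied
#' percentage, cytoplasm area) and on object areas: variance-routed group
#' comparison across timepoints, Spearman trend against the timepoint
#' order, variability test on the designated `adult_timepoints`, and the
#' regression slope across them.
#'
#' @param morpho An `eq_morphometrics` (see [morphometrics_table()]).
#' @param timepoint_order Character vector giving timepoint order; defaults
#'   to sorted unique values.
#' @param adult_timepoints Subset of timepoints for the variability and
#'   slope analyses; defaults to the last four in order.
#' @param alpha Significance level.
#' @return List of class `"eq_stats_report"` keyed by metric.
#' @export
stats_report <- function(morpho, timepoint_order = NULL,
                         adult_timepoints = NULL, alpha = 0.05) {
  cells <- morpho$cells
  if (is.null(timepoint_order)) timepoint_order <- sort(unique(cells$timepoint))
  if (is.null(adult_timepoints)) {
    adult_timepoints <- utils::tail(timepoint_order,
                                    min(4L, length(timepoint_order)))
  }
  cells$timepoint <- factor(cells$timepoint, levels = timepoint_order)
  tnum <- as.numeric(cells$timepoint)
  adult <- cells[cells$timepoint %in% adult_timepoints, , drop = FALSE]
  adult_t <- as.numeric(factor(adult$timepoint, levels = adult_timepoints))
  one_metric <- function(v, av) {
    out <- list(groups = compare_groups(v, cells$timepoint, alpha = alpha),
                trend = spearman_trend(v, tnum))
    if (length(unique(adult$timepoint)) >= 2L) {
      out$variability <- variability_test(av, adult$timepoint, alpha = alpha)
      out$slope <- slope_ci(av, adult_t)
    }
    out
  }
  rep <- list(
    n_buchnera = one_metric(cells$n_buchnera, adult$n_buchnera),
    density_per_um2 = one_metric(cells$density_per_um2, adult$density_per_um2),
    occupied_pct = one_metric(cells$occupied_pct, adult$occupied_pct),
    cytoplasm_area_um2 = one_metric(cells$cytoplasm_area_um2,
                                    adult$cytoplasm_area_um2))
  structure(rep, class = "eq_stats_report")
}
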