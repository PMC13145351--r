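#' @title Group comparison, ROC/AUC and power
#' @description
#' Diagnostic evaluation of a display-percentage biomarker: two-group
#' comparison with a normality/equal-variance gated choice between the
#' pooled t test and the Mann-Whitney U test, antibody-vs-isotype
#' specificity, ROC curves built by sweeping a threshold over the observed
#' values with strict-inequality classification, trapezoid AUC, and the
#' noncentral-t power of the two-sample design.
#' @name diagnostics_stats
NULL

# Brown-Forsythe variant of Levene's test (median-centred absolute
# deviations, one-way ANOVA F). car is not a dependency; two groups only.
levene_p <- function(a, b) {
  z <- c(abs(a - stats::median(a)), abs(b - stats::median(b)))
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  if (stats::var(z) == 0) return(1)  # no dispersion at all
  stats::oneway.test(z ~ g, var.equal = TRUE)$p.value
}

safe_shapiro_p <- function(x) {
  # identical values carry no evidence against normality but break the test
  if (length(unique(x)) < 3L) return(1)
  stats::shapiro.test(x)$p.value
}

#' Compare two groups with the assay's test-selection rule
#'
#' Runs Shapiro-Wilk normality per group and a median-centred Levene
#' (Brown-Forsythe) variance-homogeneity check. If all three pass at
#' `alpha`, a two-sided pooled-variance t test is used (`welch = TRUE`
#' switches to Welch); otherwise the two-sided Mann-Whitney U (Wilcoxon
#' rank-sum) test.
#'
#' @param a,b Numeric sample vectors, each of length >= 3 (normality is
#'   untestable below that).
#' @param alpha Gate level for the assumption checks (default 0.05).
#' @param welch Use the Welch t test instead of pooled variance.
#' @return A `group_comparison` list: group `means`, `sds`, `n`,
#'   `shapiro_p` (length 2), `levene_p`, `test_used`
#'   (`"t_test"`/`"mann_whitney_u"`), `statistic`, `p_value`.
#' @export
compare_groups <- function(a, b, alpha = 0.05, welch = FALSE) {
  if (length(a) < 3L || length(b) < 3L) {
    stop("each group needs n >= 3 (normality untestable otherwise)")
  }
  sw <- c(safe_shapiro_p(a), safe_shapiro_p(b))
  lv <- levene_p(a, b)
  parametric <- all(sw > alpha) && lv > alpha
  if (parametric) {
    ht <- stats::t.test(a, b, var.equal = !welch)
    test_used <- "t_test"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b))
    test_used <- "mann_whitney_u"
  }
  structure(list(means = c(a = mean(a), b = mean(b)),
                 sds = c(a = stats::sd(a), b = stats::sd(b)),
                 n = c(a = length(a), b = length(b)),
                 shapiro_p = sw, levene_p = lv,
                 test_used = test_used,
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> a: %.2f +/- %.2f (n=%d)  b: %.2f +/- %.2f (n=%d)\n",
              x$means[1], x$sds[1], x$n[1], x$means[2], x$sds[2], x$n[2]))
  cat(sprintf("  %s: statistic %.3f, p = %.4g\n", x$test_used, x$statistic,
              x$p_value))
  invisible(x)
}

#' Antibody-vs-isotype specificity check
#'
#' An antibody labels specifically when it labels a higher proportion of
#' EVs than its isotype control and the difference is significant: verdict
#' `specific` iff `mean(antibody) > mean(isotype)` and the two-sided
#' comparison p-value is below `alpha`. The directional requirement is
#' absolute — an antibody below its isotype is never specific, whatever
#' the p-value.
#'
#' @param antibody_vals,isotype_vals Display percentages (n >= 3 each).
#' @param alpha Significance level (default 0.05, two-sided).
#' @return A `group_comparison` with an added `specific` logical field.
#' @export
antibody_vs_isotype <- function(antibody_vals, isotype_vals, alpha = 0.05) {
  cmp <- compare_groups(antibody_vals, isotype_vals)
  cmp$specific <- unname(cmp$means[1] > cmp$means[2]) && cmp$p_value < alpha
  cmp
}

#' Choose the ROC classification direction from group means
#'
#' A biomarker elevated in the positive condition classifies positives
#' *above* the threshold; a reduced biomarker classifies them *below*.
#' An exact tie leaves the direction undefined and is an error.
#'
#' @param mean_pos,mean_neg Group means (positive = the condition to be
#'   detected).
#' @return `"positive_if_above"` or `"positive_if_below"`.
#' @export
choose_direction <- function(mean_pos, mean_neg) {
  if (!is.finite(mean_pos) || !is.finite(mean_neg)) stop("means must be finite")
  if (mean_pos == mean_neg) stop("group means tie: direction undefined")
  if (mean_pos > mean_neg) "positive_if_above" else "positive_if_below"
}

#' Build a ROC curve by threshold sweep
#'
#' Thresholds are every unique pooled sample value plus -Inf/+Inf
#' sentinels. At each threshold an observation is classified positive by
#' strict inequality on the chosen side (`> thr` for
#' `positive_if_above`, `< thr` for `positive_if_below`); TPR is the
#' fraction of positives classified positive, FPR the fraction of
#' negatives. The curve is sorted by FPR then TPR and always contains the
#' (0,0) and (1,1) corners.
#'
#' @param pos_vals,neg_vals Non-empty sample values for the positive
#'   (condition present) and negative groups.
#' @param direction See [choose_direction()].
#' @return A `roc_curve` list: `threshold`, `tpr`, `fpr` vectors (sorted
#'   along the sweep), `direction`, `n_pos`, `n_neg`.
#' @export
roc_points <- function(pos_vals, neg_vals,
                       direction = c("positive_if_above", "positive_if_below")) {
  direction <- match.arg(direction)
  if (!length(pos_vals) || !length(neg_vals)) stop("both groups must be non-empty")
  thr <- c(-Inf, sort(unique(c(pos_vals, neg_vals))), Inf)
  classify <- if (direction == "positive_if_above") {
    function(v, t) v > t
  } else {
    function(v, t) v < t
  }
  tpr <- vapply(thr, function(t) mean(classify(pos_vals, t)), 0)
  fpr <- vapply(thr, function(t) mean(classify(neg_vals, t)), 0)
  ord <- order(fpr, tpr)
  structure(list(threshold = thr[ord], tpr = tpr[ord], fpr = fpr[ord],
                 direction = direction,
                 n_pos = length(pos_vals), n_neg = length(neg_vals)),
            class = "roc_curve")
}

#' Trapezoid area under a ROC curve
#'
#' `sum((FPR2 - FPR1) * (TPR2 + TPR1) / 2)` over consecutive curve points.
#' Over the unique-value sweep this equals the tie-adjusted rank statistic
#' (ties weighted 1/2) divided by `n_pos * n_neg`.
#'
#' @param curve A `roc_curve`.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  if (is.unsorted(curve$fpr)) stop("curve must be sorted by FPR")
  k <- length(curve$fpr)
  sum((curve$fpr[-1] - curve$fpr[-k]) * (curve$tpr[-1] + curve$tpr[-k]) / 2)
}

#' Sensitivity and specificity at a threshold
#'
#' Sensitivity is the TPR at the threshold (strict inequality on the
#' chosen side); specificity is `1 - FPR`.
#'
#' @param threshold Classification threshold.
#' @inheritParams roc_points
#' @return Named numeric vector `c(sensitivity =, specificity =)`.
#' @export
sens_spec_at <- function(threshold, pos_vals, neg_vals,
                         direction = c("positive_if_above", "positive_if_below")) {
  direction <- match.arg(direction)
  if (!length(pos_vals) || !length(neg_vals)) stop("both groups must be non-empty")
  pos_hit <- if (direction == "positive_if_above") pos_vals > threshold else pos_vals < threshold
  neg_hit <- if (direction == "positive_if_above") neg_vals > threshold else neg_vals < threshold
  c(sensitivity = mean(pos_hit), specificity = 1 - mean(neg_hit))
}

#' Optimal threshold by Youden's J
#'
#' Maximises `J = TPR - FPR` over the curve; ties break toward higher
#' specificity (lower FPR), then toward lower TPR for determinism.
#'
#' @param curve A `roc_curve`.
#' @return List: `threshold`, `sensitivity`, `specificity`, `youden_j`.
#' @export
optimal_threshold <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  j <- curve$tpr - curve$fpr
  best <- which(j == max(j))
  best <- best[order(curve$fpr[best], curve$tpr[best])][1L]
  list(threshold = curve$threshold[best],
       sensitivity = curve$tpr[best],
       specificity = 1 - curve$fpr[best],
       youden_j = j[best])
}

#' Power of the two-sample pooled t test
#'
#' Design statements of the form "n per group is sufficient for 80% power
#' if the SD is 55% of the mean difference" translate to an effect size
#' `d = 1 / sd_to_diff_ratio`. Power is computed exactly from the
#' noncentral t distribution with `2n - 2` degrees of freedom and
#' noncentrality `d * sqrt(n / 2)`, two-sided at `alpha`.
#'
#' @param n_per_group Samples per group (>= 2).
#' @param sd_to_diff_ratio Common SD as a fraction of the between-group
#'   mean difference (> 0).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power in (0, 1).
#' @export
ttest_power <- function(n_per_group, sd_to_diff_ratio, alpha = 0.05) {
  stopifnot_scalar_num(n_per_group, "n_per_group", 2)
  stopifnot_scalar_num(sd_to_diff_ratio, "sd_to_diff_ratio", 0, strict = TRUE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)")
  d <- 1 / sd_to_diff_ratio
  df <- 2 * n_per_group - 2
  ncp <- d * sqrt(n_per_group / 2)
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tcrit, df, ncp) + 1 - stats::pt(tcrit, df, ncp)
}
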