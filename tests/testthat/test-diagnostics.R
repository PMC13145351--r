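test_that("compare_groups applies the test-selection rule", {
  a <- withr::with_seed(1, rnorm(20, 10, 2))
  cmp <- compare_groups(a, a)
  expect_equal(cmp$test_used, "t_test")
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 1)

  # null p-values approximately uniform when assumptions hold
  pvals <- vapply(1:400, function(s) {
    withr::with_seed(1000 + s, {
      compare_groups(rnorm(15), rnorm(15))$p_value
    })
  }, 0)
  # rank-test p-values are discrete, so KS warns about ties; harmless here
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)

  # heavy tails push the rule to the rank-sum test in most seeds
  used <- vapply(1:100, function(s) {
    withr::with_seed(2000 + s, compare_groups(rcauchy(20), rcauchy(20))$test_used)
  }, "")
  expect_gt(mean(used == "mann_whitney_u"), 0.5)

  # unequal variances trip the Levene gate even for normal data
  lv <- withr::with_seed(3, compare_groups(rnorm(50, 0, 1), rnorm(50, 0, 6)))
  expect_equal(lv$test_used, "mann_whitney_u")

  expect_error(compare_groups(c(1, 2), c(1, 2, 3)), "n >= 3")
})

test_that("antibody_vs_isotype requires direction and significance", {
  # printed cohort values: antibody 33.0 +/- 5.9 vs isotype 12.6 +/- 3.4, n=6
  hits <- vapply(1:1000, function(s) {
    withr::with_seed(s, {
      antibody_vs_isotype(rnorm(6, 33.0, 5.9), rnorm(6, 12.6, 3.4))$specific
    })
  }, TRUE)
  expect_gte(mean(hits), 0.95)

  # type I: identical distributions -> ~2.5% (one side of two-sided alpha)
  null_hits <- vapply(1:1000, function(s) {
    withr::with_seed(50000 + s, {
      antibody_vs_isotype(rnorm(6, 20, 5), rnorm(6, 20, 5))$specific
    })
  }, TRUE)
  expect_gt(mean(null_hits), 0.01)
  expect_lt(mean(null_hits), 0.045)

  # antibody below isotype is never specific, whatever the p-value
  below <- withr::with_seed(4, antibody_vs_isotype(rnorm(6, 5, 1), rnorm(6, 30, 1)))
  expect_false(below$specific)
  expect_lt(below$p_value, 0.05)
})

test_that("choose_direction follows the group means and rejects ties", {
  expect_equal(choose_direction(21.5, 33.0), "positive_if_below")
  expect_equal(choose_direction(5, 1), "positive_if_above")
  expect_error(choose_direction(2, 2), "tie")
  expect_error(choose_direction(NaN, 2), "finite")
})

test_that("roc_points matches exhaustive-threshold enumeration", {
  # perfect separation attains (FPR 0, TPR 1)
  perfect <- roc_points(c(2, 3, 4), c(0, 1), "positive_if_above")
  expect_true(any(perfect$fpr == 0 & perfect$tpr == 1))
  expect_equal(range(perfect$fpr), c(0, 1))
  expect_equal(range(perfect$tpr), c(0, 1))

  # total tie: only the two corners
  tied <- roc_points(rep(3, 4), rep(3, 5), "positive_if_above")
  expect_equal(unique(cbind(tied$fpr, tied$tpr)),
               cbind(c(0, 1), c(0, 1)))

  # random 6-vs-6: every cut agrees with brute-force counting
  for (seed in 1:20) {
    withr::with_seed(seed, {
      pos <- sample(1:8, 6, replace = TRUE)
      neg <- sample(1:8, 6, replace = TRUE)
    })
    for (direction in c("positive_if_above", "positive_if_below")) {
      curve <- roc_points(pos, neg, direction)
      for (i in seq_along(curve$threshold)) {
        t <- curve$threshold[i]
        hit <- if (direction == "positive_if_above") {
          c(mean(pos > t), mean(neg > t))
        } else {
          c(mean(pos < t), mean(neg < t))
        }
        expect_equal(c(curve$tpr[i], curve$fpr[i]), hit)
      }
      expect_false(is.unsorted(curve$fpr))
    }
  }
  expect_error(roc_points(numeric(), 1), "non-empty")
})

test_that("trapezoid AUC equals the tie-adjusted rank statistic (oracle property)", {
  expect_equal(auc(roc_points(c(2, 3, 4), c(0, 1), "positive_if_above")), 1)
  expect_equal(auc(roc_points(rep(3, 4), rep(3, 5), "positive_if_above")), 0.5)

  for (seed in 1:200) {
    withr::with_seed(seed, {
      n1 <- sample(3:10, 1); n2 <- sample(3:10, 1)
      pos <- sample(1:6, n1, replace = TRUE) + round(rnorm(n1), 1)
      neg <- sample(1:6, n2, replace = TRUE) + round(rnorm(n2), 1)
    })
    for (direction in c("positive_if_above", "positive_if_below")) {
      a <- auc(roc_points(pos, neg, direction))
      expect_equal(a, mwu_auc(pos, neg, direction))
    }
  }
})

test_that("AUC respects label/direction symmetry", {
  for (seed in 1:25) {
    withr::with_seed(seed, {
      pos <- rnorm(7, 1); neg <- rnorm(9)
    })
    a <- auc(roc_points(pos, neg, "positive_if_above"))
    # swap groups and flip direction: AUC invariant
    expect_equal(auc(roc_points(neg, pos, "positive_if_below")), a)
    # swap groups, direction fixed: AUC complements
    expect_equal(auc(roc_points(neg, pos, "positive_if_above")), 1 - a)
  }
})

test_that("sens_spec_at counts strictly and complements FPR", {
  pos <- c(4, 5, 6); neg <- c(1, 2, 3)
  expect_equal(sens_spec_at(0, pos, neg, "positive_if_above"),
               c(sensitivity = 1, specificity = 0))
  expect_equal(sens_spec_at(10, pos, neg, "positive_if_above"),
               c(sensitivity = 0, specificity = 1))
  for (seed in 1:10) {
    withr::with_seed(seed, {
      p <- sample(1:6, 6, replace = TRUE)
      n <- sample(1:6, 6, replace = TRUE)
      t <- sample(1:6, 1)
    })
    ss <- sens_spec_at(t, p, n, "positive_if_below")
    expect_equal(unname(ss["sensitivity"]), sum(p < t) / 6)
    expect_equal(unname(ss["specificity"]), 1 - sum(n < t) / 6)
  }
})

test_that("optimal_threshold maximises Youden J with high-specificity ties", {
  perfect <- optimal_threshold(roc_points(c(5, 6), c(1, 2), "positive_if_above"))
  expect_equal(perfect$youden_j, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  tied <- optimal_threshold(roc_points(rep(3, 3), rep(3, 3), "positive_if_above"))
  expect_equal(tied$youden_j, 0)
  expect_equal(tied$specificity, 1)  # corner chosen by the tie rule

  for (seed in 1:20) {
    withr::with_seed(seed, {
      pos <- rnorm(6, 1); neg <- rnorm(6)
    })
    curve <- roc_points(pos, neg, "positive_if_above")
    opt <- optimal_threshold(curve)
    expect_equal(opt$youden_j, max(curve$tpr - curve$fpr))  # brute-force scan
  }
})

test_that("ttest_power matches theory, limits and Monte Carlo", {
  # the 6x6 design claim: SD 55% of the difference gives at least 80% power
  expect_gte(ttest_power(6, 0.55), 0.80)
  # vanishing effect: power collapses to alpha
  expect_equal(ttest_power(6, 1e6), 0.05, tolerance = 1e-3)
  # cross-check against stats::power.t.test
  expect_equal(ttest_power(6, 0.55),
               stats::power.t.test(n = 6, delta = 1, sd = 0.55)$power,
               tolerance = 1e-6)

  # monotone in n, antitone in the SD ratio
  expect_true(all(diff(vapply(3:12, ttest_power, 0, sd_to_diff_ratio = 0.55)) > 0))
  expect_true(all(diff(vapply(seq(0.3, 1.2, 0.1), function(r)
    ttest_power(6, r), 0)) < 0))

  # Monte Carlo oracle: 1e5 simulated pooled t tests at n = 6, d = 1/0.55
  d <- 1 / 0.55
  reps <- 1e5
  withr::with_seed(1234, {
    x <- matrix(rnorm(reps * 6, d), reps)
    y <- matrix(rnorm(reps * 6, 0), reps)
  })
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- (rowSums(x^2) - 6 * mx^2) / 5
  vy <- (rowSums(y^2) - 6 * my^2) / 5
  tstat <- (mx - my) / sqrt((vx + vy) / 2 * (2 / 6))
  mc_power <- mean(abs(tstat) > qt(0.975, 10))
  expect_equal(ttest_power(6, 0.55), mc_power, tolerance = 0.01)
})
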