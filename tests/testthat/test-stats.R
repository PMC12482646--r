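test_that("effect size has the pooled-SD algebraic properties", {
  set.seed(31)
  a <- rnorm(40, 10, 2); b <- rnorm(25, 3, 3)
  d <- effect_size(a, b)
  # antisymmetric under group swap
  expect_equal(effect_size(b, a), -d, tolerance = 1e-12)
  # invariant under a common shift
  expect_equal(effect_size(a + 100, b + 100), d, tolerance = 1e-12)
  # invariant under common positive scaling
  expect_equal(effect_size(3 * a, 3 * b), d, tolerance = 1e-12)
  # identical groups give 0
  expect_equal(effect_size(a, a), 0)
  # summary and raw-sample interfaces agree
  expect_equal(effect_size(group_summary(mean(a), sd(a), length(a)),
                           group_summary(mean(b), sd(b), length(b))),
               d, tolerance = 1e-12)
})

test_that("the two variance conventions differ as (N-1)/N", {
  p <- group_summary(10, 2, 30); n <- group_summary(0, 2, 20)
  d_sample <- effect_size(p, n, variance = "sample")
  d_pop <- effect_size(p, n, variance = "population")
  pooled_s <- (29 * 4 + 19 * 4) / 48
  pooled_p <- (30 * 4 + 20 * 4) / 48
  expect_equal(d_sample, 10 / sqrt(pooled_s), tolerance = 1e-12)
  expect_equal(d_pop, 10 / sqrt(pooled_p), tolerance = 1e-12)
  expect_gt(d_sample, d_pop)
})

test_that("bootstrap CI is seeded, covering, and narrows with n", {
  set.seed(77)
  pos <- rnorm(60, 85, 28); neg <- rnorm(20, 1, 3.6)
  ci1 <- bootstrap_effect_size_ci(pos, neg, n_boot = 2000, seed = 5)
  ci2 <- bootstrap_effect_size_ci(pos, neg, n_boot = 2000, seed = 5)
  expect_identical(ci1, ci2)                      # bit-for-bit under a seed
  expect_lte(ci1$ci_low, ci1$d)
  expect_gte(ci1$ci_high, ci1$d)
  # independent seed agrees within Monte-Carlo tolerance
  ci3 <- bootstrap_effect_size_ci(pos, neg, n_boot = 10000, seed = 6)
  ci4 <- bootstrap_effect_size_ci(pos, neg, n_boot = 10000, seed = 7)
  expect_lt(abs(ci3$ci_low - ci4$ci_low), 0.05)
  expect_lt(abs(ci3$ci_high - ci4$ci_high), 0.05)
  # width shrinks from n = 30 to n = 300 per group
  set.seed(78)
  w <- vapply(c(30, 300), function(n) {
    ci <- bootstrap_effect_size_ci(rnorm(n, 5, 2), rnorm(n, 0, 2),
                                   n_boot = 1500, seed = 9)
    ci$ci_high - ci$ci_low
  }, numeric(1))
  expect_lt(w[2], w[1])
  # near-point-mass groups: as within-group jitter vanishes the whole
  # bootstrap distribution of the standardized separation diverges (the
  # interval stays relatively tight around an ever-larger d), so the lower
  # bound scales like 1/jitter
  lower_at <- function(jitter) {
    p <- 10 + rnorm(30, sd = jitter); n <- rnorm(30, sd = jitter)
    bootstrap_effect_size_ci(p, n, n_boot = 500, seed = 2)$ci_low
  }
  set.seed(79)
  expect_gt(lower_at(1e-6), 100 * lower_at(1e-3))
})

test_that("Levene statistic equals the brute-force ANOVA on |x - mean|", {
  set.seed(19)
  groups <- list(a = rnorm(15, 0, 1), b = rnorm(20, 0, 2),
                 c = rnorm(12, 1, 1.5))
  out <- levene_test(groups)
  # textbook one-way ANOVA F on absolute deviations, by hand
  z <- lapply(groups, function(g) abs(g - mean(g)))
  zall <- unlist(z); k <- length(z); N <- length(zall)
  zbar <- mean(zall)
  ssb <- sum(vapply(z, function(zi) length(zi) * (mean(zi) - zbar)^2,
                    numeric(1)))
  ssw <- sum(vapply(z, function(zi) sum((zi - mean(zi))^2), numeric(1)))
  f_oracle <- (ssb / (k - 1)) / (ssw / (N - k))
  expect_equal(out$levene_stat, f_oracle, tolerance = 1e-12)
  expect_equal(out$levene_p, pf(f_oracle, k - 1, N - k, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("Levene cross-checks against car and detects unequal variance", {
  skip_if_not_installed("car")
  set.seed(23)
  x1 <- rnorm(200, 0, 1); x2 <- rnorm(200, 0, 3)
  out <- levene_test(list(a = x1, b = x2))
  ref <- car::leveneTest(c(x1, x2), factor(rep(1:2, each = 200)),
                         center = mean)
  expect_equal(out$levene_stat, ref[1, "F value"], tolerance = 1e-10)
  expect_lt(out$levene_p, 0.01)
  # same spread around different centres: statistic 0
  sym <- list(a = c(1, 2, 3), b = c(11, 12, 13))
  expect_equal(levene_test(sym)$levene_stat, 0, tolerance = 1e-12)
  # all values identical overall: degenerate p = 1 convention
  same <- list(a = c(2, 2, 2), b = c(2, 2, 2))
  expect_equal(levene_test(same)$levene_p, 1)
})

test_that("pairwise F tests match the F distribution and Bonferroni rule", {
  set.seed(29)
  g <- list(a = rnorm(100, sd = 1), b = rnorm(100, sd = 2),
            c = rnorm(100, sd = 1))
  out <- pairwise_f_tests(g)
  expect_equal(nrow(out), 3)
  # adjusted never below raw and never above 1
  expect_true(all(out$p_adj >= out$p_raw))
  expect_true(all(out$p_adj <= 1))
  expect_equal(out$p_adj, pmin(1, out$p_raw * 3), tolerance = 1e-12)
  # variance ratio 4 at n = 100 vs 100 is decisively rejected
  ab <- out[out$group1 == "a" & out$group2 == "b", ]
  expect_lt(ab$p_raw, 0.001)
  # direct F-distribution oracle for one pair
  f <- var(g$a) / var(g$b)
  p_oracle <- 2 * min(pf(f, 99, 99), pf(f, 99, 99, lower.tail = FALSE))
  expect_equal(ab$p_raw, p_oracle, tolerance = 1e-10)
  # equal-variance pair is unremarkable
  ac <- out[out$group1 == "a" & out$group2 == "c", ]
  expect_gt(ac$p_adj, 0.05)
  expect_error(pairwise_f_tests(g, list(c("a", "zz"))), "unknown group")
})

test_that("ROC handles perfect separation and monotonicity", {
  scores <- c(1, 2, 3, 10, 11, 12)
  labels <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  r <- roc_analysis(scores, labels)
  expect_equal(r$auc, 1)
  expect_equal(r$j_max, 1)
  expect_equal(r$accuracy, 1)
  expect_gt(r$optimal_threshold, 3); expect_lt(r$optimal_threshold, 10)
  # sens non-increasing, spec non-decreasing in the threshold
  ord <- order(r$thresholds)
  expect_true(all(diff(r$sens[ord]) <= 1e-12))
  expect_true(all(diff(r$spec[ord]) >= -1e-12))
  expect_error(roc_analysis(scores, rep(TRUE, 6)), "both classes")
})

test_that("trapezoidal AUC equals the Mann-Whitney rank statistic", {
  set.seed(41)
  for (i in 1:200) {
    n_pos <- sample(3:25, 1); n_neg <- sample(3:25, 1)
    scores <- c(rnorm(n_pos, mean = runif(1, 0, 2)), rnorm(n_neg))
    labels <- rep(c(TRUE, FALSE), c(n_pos, n_neg))
    r <- roc_analysis(scores, labels)
    # U statistic with the tie convention of the ROC curve
    u <- sum(vapply(scores[labels], function(s)
      sum(s > scores[!labels]) + 0.5 * sum(s == scores[!labels]),
      numeric(1)))
    expect_equal(r$auc, u / (n_pos * n_neg), tolerance = 1e-10)
  }
})

test_that("AUC agrees with pROC and is ~0.5 for uninformative scores", {
  skip_if_not_installed("pROC")
  set.seed(43)
  scores <- rnorm(300); labels <- rep(c(TRUE, FALSE), 150)
  r <- roc_analysis(scores, labels)
  ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores,
                                              direction = "<")))
  expect_equal(r$auc, as.numeric(ref), tolerance = 1e-10)
  expect_lt(abs(r$auc - 0.5), 0.08)
})

test_that("Youden tie-break prefers the higher-specificity cutoff", {
  # thresholds 1.5 and 3.5 both reach J = 0.5; the higher-specificity one
  # (3.5, no false positives) must be chosen
  scores <- c(1, 2, 3, 4)
  labels <- c(FALSE, TRUE, FALSE, TRUE)
  r <- roc_analysis(scores, labels)
  expect_equal(r$j_max, 0.5)
  expect_equal(r$optimal_threshold, 3.5)
  expect_equal(r$specificity, 1)
})

test_that("Youden cutoff lands in the generator decision band", {
  man <- cohort_manifest(make_cohort(
    cohort_spec(n_per_group = c(YC = 23, Abeta_negative = 76, ADCI = 207),
                seed = 47L), volumes = FALSE))
  r <- roc_analysis(man$true_cl, man$visual_read)
  lo <- max(man$true_cl[!man$visual_read])
  hi <- min(man$true_cl[man$visual_read])
  expect_gt(r$optimal_threshold, lo)
  expect_lte(r$optimal_threshold, hi)
  expect_equal(r$j_max, 1)
})
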