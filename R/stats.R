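#' Group summary
#'
#' Mean, SD and count of one cohort group; the SD is the sample SD
#' (N - 1 denominator), the form in which group summaries are reported.
#'
#' @param mean group mean (CL or SUVR units).
#' @param sd sample standard deviation (>= 0).
#' @param n group size (>= 2).
#' @return an object of class `group_summary`.
#' @export
group_summary <- function(mean, sd, n) {
  if (n < 2) stop("group needs n >= 2", call. = FALSE)
  if (sd < 0) stop("sd must be >= 0", call. = FALSE)
  structure(list(mean = mean, sd = sd, n = as.integer(n)),
            class = "group_summary")
}

as_group_summary <- function(x) {
  if (inherits(x, "group_summary")) return(x)
  if (is.numeric(x))
    return(group_summary(mean(x), stats::sd(x), length(x)))
  stop("expected a group_summary or a numeric sample", call. = FALSE)
}

#' Pooled-SD effect size between two groups
#'
#' Computes `d = (mu_p - mu_n) / sqrt((Np * var_p + Nn * var_n) /
#' (Np + Nn - 2))`. The variances entering the numerator of the pooled
#' term are population variances; printed group SDs are sample SDs, so
#' under the default `variance = "sample"` convention the products are
#' computed as `(N - 1) * s^2`, which makes the statistic the classic
#' pooled-SD (Cohen's d / Hedges) form. `variance = "population"` takes
#' the given SDs at face value (`N * sd^2`).
#'
#' @param pos,neg positive/negative groups: `group_summary` objects or raw
#'   numeric samples (summaries are computed first).
#' @param variance `"sample"` (default) or `"population"`; see Details.
#' @return the effect size (dimensionless scalar).
#' @export
effect_size <- function(pos, neg, variance = c("sample", "population")) {
  variance <- match.arg(variance)
  pos <- as_group_summary(pos); neg <- as_group_summary(neg)
  np <- pos$n; nn <- neg$n
  if (np + nn <= 2) stop("need Np + Nn > 2", call. = FALSE)
  wp <- if (variance == "sample") np - 1 else np
  wn <- if (variance == "sample") nn - 1 else nn
  pooled <- (wp * pos$sd^2 + wn * neg$sd^2) / (np + nn - 2)
  (pos$mean - neg$mean) / sqrt(pooled)
}

#' Bootstrap percentile CI for the effect size
#'
#' Non-parametric bootstrap: each group is resampled with replacement at
#' its own size, the effect size recomputed, and the 2.5/97.5 percentiles
#' of the resampled statistics returned (percentile interval, 10,000
#' resamples by default). Degenerate resamples with zero pooled variance
#' are skipped and counted.
#'
#' @param pos_samples,neg_samples numeric vectors (>= 2 values each).
#' @param n_boot number of resamples.
#' @param seed integer seed; the draw is fully reproducible.
#' @param conf confidence level.
#' @param variance passed to [effect_size()].
#' @return an object of class `effect_size_ci`: list with `d`, `ci_low`,
#'   `ci_high`, `n_boot`, `n_skipped`, `seed`.
#' @export
bootstrap_effect_size_ci <- function(pos_samples, neg_samples,
                                     n_boot = 10000, seed = 1L,
                                     conf = 0.95,
                                     variance = c("sample", "population")) {
  variance <- match.arg(variance)
  if (length(pos_samples) < 2 || length(neg_samples) < 2)
    stop("each group needs >= 2 observations", call. = FALSE)
  d_obs <- effect_size(pos_samples, neg_samples, variance)
  np <- length(pos_samples); nn <- length(neg_samples)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      p <- pos_samples[sample.int(np, np, replace = TRUE)]
      n <- neg_samples[sample.int(nn, nn, replace = TRUE)]
      if (stats::var(p) == 0 && stats::var(n) == 0) return(NA_real_)
      effect_size(p, n, variance)
    }, numeric(1))
  })
  skipped <- sum(is.na(boot))
  q <- stats::quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                       na.rm = TRUE, names = FALSE)
  structure(list(d = d_obs, ci_low = q[1], ci_high = q[2],
                 n_boot = n_boot, n_skipped = skipped, seed = seed,
                 conf = conf),
            class = "effect_size_ci")
}

#' @export
print.effect_size_ci <- function(x, ...) {
  cat(sprintf("effect size %.2f (%.0f%% bootstrap CI %.2f-%.2f, %d resamples)\n",
              x$d, 100 * x$conf, x$ci_low, x$ci_high, x$n_boot))
  if (x$n_skipped > 0)
    cat(sprintf("  (%d degenerate resamples skipped)\n", x$n_skipped))
  invisible(x)
}

#' Levene's test for homogeneity of variance
#'
#' Classic Levene statistic: a one-way ANOVA F test on the absolute
#' deviations from each group's mean (`center = "mean"`). The
#' median-centred Brown-Forsythe variant is available via
#' `center = "median"`.
#'
#' @param groups named list of numeric samples (>= 2 groups, each n >= 2).
#' @param center `"mean"` (default) or `"median"`.
#' @return an object of class `variance_report` with `levene_stat`,
#'   `levene_p`, `df`.
#' @export
levene_test <- function(groups, center = c("mean", "median")) {
  center <- match.arg(center)
  if (length(groups) < 2 || any(vapply(groups, length, 1L) < 2))
    stop("need >= 2 groups with n >= 2 each", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  if (length(unique(x)) == 1L) {
    out <- list(levene_stat = 0, levene_p = 1,
                df = c(length(groups) - 1L, length(x) - length(groups)),
                center = center, degenerate = TRUE)
    class(out) <- "variance_report"
    return(out)
  }
  ctr <- if (center == "mean") tapply(x, g, mean) else tapply(x, g, stats::median)
  z <- abs(x - ctr[g])
  fit <- stats::aov(z ~ g)
  tab <- summary(fit)[[1]]
  structure(list(levene_stat = tab[["F value"]][1],
                 levene_p = tab[["Pr(>F)"]][1],
                 df = c(tab[["Df"]][1], tab[["Df"]][2]),
                 center = center, degenerate = FALSE),
            class = "variance_report")
}

#' @export
print.variance_report <- function(x, ...) {
  cat(sprintf("Levene's test (center = %s): F(%d, %d) = %.4g, p = %.4g\n",
              x$center, x$df[1], x$df[2], x$levene_stat, x$levene_p))
  invisible(x)
}

#' Pairwise variance-ratio F tests with Bonferroni correction
#'
#' Two-sided F tests of equal variance for each named pair of groups;
#' p-values are Bonferroni-adjusted over the requested comparisons
#' (`p_adj = min(1, p * K)`).
#'
#' @param groups named list of numeric samples.
#' @param comparisons list of length-2 character vectors naming the pairs;
#'   default is all pairs.
#' @param alpha significance level recorded in the report.
#' @return a data frame with one row per comparison: group names, variance
#'   ratio `f`, degrees of freedom, `p_raw`, `p_adj`, `significant`.
#' @export
pairwise_f_tests <- function(groups, comparisons = NULL, alpha = 0.05) {
  if (is.null(comparisons)) {
    nm <- names(groups)
    comparisons <- utils::combn(nm, 2, simplify = FALSE)
  }
  bad <- setdiff(unique(unlist(comparisons)), names(groups))
  if (length(bad))
    stop("unknown group(s): ", paste(bad, collapse = ", "), call. = FALSE)
  rows <- lapply(comparisons, function(cmp) {
    a <- groups[[cmp[1]]]; b <- groups[[cmp[2]]]
    if (stats::var(a) == 0 || stats::var(b) == 0)
      stop("zero variance in group ", cmp[which(c(stats::var(a),
                                                  stats::var(b)) == 0)[1]],
           call. = FALSE)
    ft <- stats::var.test(a, b)
    data.frame(group1 = cmp[1], group2 = cmp[2],
               f = unname(ft$statistic),
               df1 = unname(ft$parameter[1]), df2 = unname(ft$parameter[2]),
               p_raw = ft$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p_raw * nrow(out))
  out$significant <- out$p_adj < alpha
  out
}

#' ROC analysis with Youden-optimal cutoff
#'
#' High scores are treated as positive; a score is called positive iff it
#' is greater than or equal to the threshold. Candidate thresholds are the
#' midpoints between consecutive distinct scores plus -Inf/+Inf sentinels.
#' AUC is the trapezoidal area over (1 - specificity, sensitivity). The
#' optimal cutoff maximises Youden's J = sensitivity + specificity - 1;
#' among ties the threshold with the highest specificity is chosen
#' (fewest false positives).
#'
#' @param scores numeric scores (e.g. Centiloid values).
#' @param labels logical (or 0/1) true-positive indicators; both classes
#'   must be present.
#' @return an object of class `roc_result`: `thresholds`, `sens`, `spec`,
#'   `auc`, `optimal_threshold`, `j_max`, and `accuracy`, `sensitivity`,
#'   `specificity` at the optimum.
#' @export
roc_analysis <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present", call. = FALSE)

  s <- sort(unique(scores))
  thresholds <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  sens <- vapply(thresholds, function(t) sum(scores >= t & labels) / n_pos,
                 numeric(1))
  spec <- vapply(thresholds, function(t) sum(scores < t & !labels) / n_neg,
                 numeric(1))

  fpr <- 1 - spec
  ord <- order(fpr, sens)
  auc <- sum(diff(fpr[ord]) * (sens[ord][-1] + sens[ord][-length(ord)]) / 2)

  j <- sens + spec - 1
  j_max <- max(j)
  cand <- which(j >= j_max - 1e-12)
  best <- cand[which.max(spec[cand])]
  opt <- thresholds[best]
  acc <- (sum(scores >= opt & labels) + sum(scores < opt & !labels)) /
    length(scores)
  structure(list(thresholds = thresholds, sens = sens, spec = spec,
                 auc = auc, optimal_threshold = opt, j_max = j_max,
                 accuracy = acc, sensitivity = sens[best],
                 specificity = spec[best],
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (n+ = %d, n- = %d)\n", x$auc, x$n_pos,
              x$n_neg))
  cat(sprintf("  Youden-optimal cutoff %.4g (J = %.3f): accuracy %.3f, sensitivity %.3f, specificity %.3f\n",
              x$optimal_threshold, x$j_max, x$accuracy, x$sensitivity,
              x$specificity))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(1 - x$spec, x$sens, type = "l", xlab = "1 - specificity",
                 ylab = "sensitivity", xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(a = 0, b = 1, lty = 2)
  invisible(x)
}

#' @rdname roc_analysis
#' @param x a `roc_result`.
#' @return `roc_points` returns the curve as a data frame
#'   (`threshold`, `sensitivity`, `specificity`) for export/plotting.
#' @export
roc_points <- function(x) {
  stopifnot(inherits(x, "roc_result"))
  data.frame(threshold = x$thresholds, sensitivity = x$sens,
             specificity = x$spec)
}
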