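#' @title Agreement and validity statistics
#'
#' @description
#' Concurrent validity of the instrumented spine against the optical
#' reference is quantified four ways: root-mean-square error with the
#' McGinley-style interpretation bands (good <= 2 deg, acceptable <= 5 deg,
#' tolerable <= 10 deg, unbearable beyond), Bland-Altman bias and 95% limits
#' of agreement on randomly sampled paired points, parallel-forms
#' reliability (Pearson r between the two systems' scores) converted to a
#' standard error of measurement `SEM = SD * sqrt(1 - r)` and a minimal
#' detectable change `MDC95 = 1.96 * sqrt(2) * SEM`, and a one-sided
#' non-inferiority t-test of fast-vs-slow RMSE against an MDC-based margin.
#'
#' @name agreement
NULL

#' Root-mean-square error between paired angle series
#'
#' @param x1,x2 equal-length numeric vectors in degrees (measurement and
#'   reference).
#' @return RMSE in degrees.
#' @export
rmse <- function(x1, x2) {
  if (length(x1) != length(x2)) stopf("paired series differ in length")
  if (!length(x1)) stopf("empty series")
  sqrt(mean((x1 - x2)^2))
}

RMSE_BANDS <- c(Good = 2, Acceptable = 5, Tolerable = 10, Unbearable = Inf)

#' Interpretation band of an RMSE value
#'
#' Boundaries are inclusive on the left band as conventionally printed:
#' exactly 2 degrees is still "Good".
#'
#' @param value RMSE in degrees (vectorised, non-negative).
#' @return factor with levels Good, Acceptable, Tolerable, Unbearable.
#' @export
interpret_rmse <- function(value) {
  if (any(value < 0)) stopf("RMSE cannot be negative")
  idx <- vapply(value, function(v) which(v <= RMSE_BANDS)[1], 1L)
  factor(names(RMSE_BANDS)[idx], levels = names(RMSE_BANDS))
}

#' Random paired samples from a trial
#'
#' Draws `k` paired points uniformly without replacement, reproducibly for a
#' given seed. Sampling a fixed count per trial gives fast and slow trials
#' equal weight in pooled analyses regardless of their duration.
#'
#' @param x1,x2 equal-length paired vectors.
#' @param k points to draw (default 10).
#' @param seed integer seed.
#' @return list with `idx`, `x1`, `x2`.
#' @export
sample_points <- function(x1, x2, k = 10, seed = 1) {
  if (length(x1) != length(x2)) stopf("paired series differ in length")
  n <- length(x1)
  if (n < k) stopf("cannot sample %d points from %d valid pairs", k, n)
  idx <- sort(withr::with_seed(as.integer(seed), sample.int(n, k)))
  list(idx = idx, x1 = x1[idx], x2 = x2[idx])
}

#' Bland-Altman agreement analysis
#'
#' Bias is the mean difference `x1 - x2`; the 95% limits of agreement are
#' `bias +/- 1.96 * SD` of the differences (sample SD). Normality of the
#' differences is screened with a Shapiro-Wilk test using the reporting
#' convention `W > 0.96`; the gate is soft -- a low W is flagged, not fatal,
#' since the limits remain descriptively useful for approximately normal
#' differences.
#'
#' @param x1,x2 paired vectors in degrees (n >= 3).
#' @return list: `bias`, `sd_diff`, `loa_low`, `loa_high`, `shapiro_W`,
#'   `normality_ok`, `degenerate`, `n`.
#' @export
bland_altman <- function(x1, x2) {
  if (length(x1) != length(x2)) stopf("paired series differ in length")
  d <- x1 - x2
  if (length(d) < 3) stopf("Bland-Altman needs at least 3 pairs")
  bias <- mean(d)
  s <- stats::sd(d)
  degenerate <- s < 1e-12
  W <- if (degenerate) NA_real_ else
    unname(stats::shapiro.test(if (length(d) > 5000) d[seq(1, length(d), length.out = 5000)] else d)$statistic)
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 shapiro_W = W,
                 normality_ok = if (degenerate) TRUE else W > 0.96,
                 degenerate = degenerate, n = length(d)),
            class = "bland_altman")
}

#' Standard error of measurement from reliability
#'
#' `SEM = SD * sqrt(1 - r)`: the score spread scaled by the unreliable
#' fraction of its variance.
#'
#' @param sd standard deviation of the measured scores (degrees).
#' @param r reliability coefficient in `[-1, 1]`.
#' @return SEM in degrees.
#' @export
sem_parallel_forms <- function(sd, r) {
  if (any(r > 1 | r < -1)) stopf("reliability must lie in [-1, 1]")
  sd * sqrt(1 - r)
}

#' Minimal detectable change at 95% confidence
#'
#' `MDC95 = 1.96 * sqrt(2) * SEM`: the smallest change distinguishable from
#' measurement error of two repeated measurements at 95% confidence.
#'
#' @param sem standard error of measurement (degrees).
#' @return MDC95 in degrees.
#' @export
mdc95 <- function(sem) 1.96 * sqrt(2) * sem

#' Parallel-forms reliability, SEM and MDC of paired scores
#'
#' The two measurement systems are treated as parallel forms of the same
#' test: `r` is the Pearson correlation between their scores, `sd` the
#' sample standard deviation of the pooled motion scores (both systems),
#' and SEM/MDC95 follow from the standard formulas.
#'
#' @param x1,x2 paired score vectors in degrees (n >= 3, non-degenerate).
#' @return list: `r`, `sd`, `sem`, `mdc95`, `n`.
#' @export
reliability_sem_mdc <- function(x1, x2) {
  if (length(x1) != length(x2)) stopf("paired series differ in length")
  if (length(x1) < 3) stopf("reliability needs at least 3 pairs")
  if (stats::sd(x1) < 1e-12 || stats::sd(x2) < 1e-12) {
    stopf("reliability undefined: a score series has zero variance")
  }
  r <- stats::cor(x1, x2)
  s <- stats::sd(c(x1, x2))
  sem <- sem_parallel_forms(s, r)
  list(r = r, sd = s, sem = sem, mdc95 = mdc95(sem), n = length(x1))
}

#' One-sided non-inferiority test of motion speed
#'
#' Tests whether fast-motion accuracy is non-inferior to slow-motion
#' accuracy: H0 `mean(RMSE_fast) - mean(RMSE_slow) >= threshold` against
#' H1 that the difference is below the threshold, using a one-sided
#' two-sample t-test (Welch by default; the threshold is typically the
#' segment's minimal detectable change). Rejecting H0 means speed has no
#' practically relevant influence on accuracy.
#'
#' @param rmse_fast,rmse_slow per-trial RMSE values (degrees), >= 2 each.
#' @param threshold non-inferiority margin in degrees (> 0).
#' @param alpha one-sided type I error level (default 0.025).
#' @param paired use a paired test (requires equal lengths).
#' @return list: `mean_diff`, `threshold`, `t_stat`, `p_value`, `alpha`,
#'   `reject_h0`, `degenerate`.
#' @export
noninferiority_speed <- function(rmse_fast, rmse_slow, threshold,
                                 alpha = 0.025, paired = FALSE) {
  if (length(rmse_fast) < 2 || length(rmse_slow) < 2) {
    stopf("need at least 2 RMSE values per speed group")
  }
  if (threshold <= 0) stopf("non-inferiority threshold must be positive")
  mean_diff <- mean(rmse_fast) - mean(rmse_slow)
  degenerate <- stats::sd(rmse_fast) < 1e-12 && stats::sd(rmse_slow) < 1e-12
  if (degenerate) {
    reject <- mean_diff < threshold
    return(list(mean_diff = mean_diff, threshold = threshold,
                t_stat = NA_real_, p_value = as.numeric(!reject),
                alpha = alpha, reject_h0 = reject, degenerate = TRUE))
  }
  tt <- stats::t.test(rmse_fast, rmse_slow, mu = threshold,
                      alternative = "less", paired = paired)
  list(mean_diff = mean_diff, threshold = threshold,
       t_stat = unname(tt$statistic), p_value = tt$p.value, alpha = alpha,
       reject_h0 = tt$p.value < alpha, degenerate = FALSE)
}
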