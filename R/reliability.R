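# Test-retest reliability and agreement statistics.

#' Intraclass correlation ICC(2,1): single measures, absolute agreement
#'
#' Computed from the two-way ANOVA mean squares with k = 2 sessions:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`, with the F-based
#' 95% confidence interval of McGraw & Wong. The same mean-squares formula
#' serves the two-way random ("ICC(2,1)") and two-way mixed absolute-
#' agreement single-measures coefficients, whose values coincide.
#'
#' @param test,retest paired measurements, equal length n >= 2.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return A list with `icc`, `ci` (lower, upper), `n`, and the mean squares
#'   `msr`, `msc`, `mse`.
#' @export
icc_2_1 <- function(test, retest, conf_level = 0.95) {
  stopifnot(length(test) == length(retest))
  n <- length(test)
  if (n < 2L) stop("need at least 2 paired subjects")
  x <- cbind(test, retest)
  if (any(!is.finite(x))) stop("paired values must be finite")
  k <- 2L
  grand <- mean(x)
  row_m <- rowMeans(x)
  col_m <- colMeans(x)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom <= 0) stop("zero total variance; ICC undefined")
  icc <- (msr - mse) / denom

  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = icc, ci = c(lower = lower, upper = upper), n = n,
       msr = msr, msc = msc, mse = mse)
}

#' Reliability category for an ICC value
#'
#' Bands: 0.00-0.40 poor, 0.41-0.75 fair to good, 0.76-1.00 good to
#' excellent.
#'
#' @param icc ICC value.
#' @export
icc_category <- function(icc) {
  ifelse(icc <= 0.40, "poor",
         ifelse(icc <= 0.75, "fair-to-good", "good-to-excellent"))
}

#' Standard error of measurement and smallest detectable difference
#'
#' `SEM = sd * sqrt(1 - ICC)` and `SDD = SEM * 1.96 * sqrt(2)`. Which
#' standard deviation feeds the SEM (test, retest or pooled) is the caller's
#' choice; the pipeline uses the pooled test/retest SD.
#'
#' @param sd standard deviation in metric units, >= 0.
#' @param icc ICC(2,1) value, <= 1.
#' @return A list with `sem` and `sdd`.
#' @export
sem_sdd <- function(sd, icc) {
  if (sd < 0) stop("`sd` must be >= 0")
  if (icc > 1) stop("`icc` must be <= 1")
  sem <- sd * sqrt(1 - icc)
  list(sem = sem, sdd = sem * 1.96 * sqrt(2))
}

#' Bland-Altman agreement statistics
#'
#' Differences are `retest - test`; limits of agreement are
#' `mean(d) +/- 1.96 * sd(d)` with the sample (n - 1) standard deviation.
#' `loa_from_stats()` applies the same arithmetic to externally supplied
#' moments.
#'
#' @param test,retest paired measurements, equal length n >= 2.
#' @return A list with `mean_diff`, `sd_diff` and `loa` (lower, upper).
#' @export
bland_altman <- function(test, retest) {
  stopifnot(length(test) == length(retest))
  if (length(test) < 2L) stop("need at least 2 pairs")
  d <- retest - test
  loa_from_stats(mean(d), stats::sd(d))
}

#' @rdname bland_altman
#' @param mean_diff mean difference (retest - test).
#' @param sd_diff standard deviation of the differences.
#' @export
loa_from_stats <- function(mean_diff, sd_diff) {
  if (sd_diff < 0) stop("`sd_diff` must be >= 0")
  list(mean_diff = mean_diff, sd_diff = sd_diff,
       loa = c(lower = mean_diff - 1.96 * sd_diff,
               upper = mean_diff + 1.96 * sd_diff))
}

#' Correlation with distribution-dependent method choice
#'
#' Shapiro-Wilk normality at alpha = 0.05 on both variables selects Pearson
#' (both normal) or Spearman, unless `force_method` is given. The correlation
#' category follows the bands r < 0.30 low, 0.30 <= r < 0.45 moderate,
#' 0.45 <= r < 0.60 substantial, r >= 0.60 high.
#'
#' @param x,y numeric vectors, equal length >= 3.
#' @param force_method `"pearson"` or `"spearman"` to skip the normality
#'   check.
#' @return A list with `r`, `p`, `method`, `category`.
#' @export
correlate <- function(x, y, force_method = NULL) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input")
  }
  if (is.null(force_method)) {
    normal <- stats::shapiro.test(x)$p.value >= 0.05 &&
      stats::shapiro.test(y)$p.value >= 0.05
    method <- if (normal) "pearson" else "spearman"
  } else {
    method <- match.arg(force_method, c("pearson", "spearman"))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method, exact = FALSE))
  list(r = unname(ct$estimate), p = ct$p.value, method = method,
       category = correlation_category(unname(ct$estimate)))
}

#' @rdname correlate
#' @param r correlation coefficient.
#' @export
correlation_category <- function(r) {
  ifelse(r < 0.30, "low",
         ifelse(r < 0.45, "moderate",
                ifelse(r < 0.60, "substantial", "high")))
}

#' Paired difference between target and unaffected regions
#'
#' Two-sided paired t-test; returns the mean difference (target minus
#' unaffected), its standard error, and the p-value. Identical groups return
#' a zero difference with p = 1 by convention.
#'
#' @param target,unaffected paired values, equal length >= 2.
#' @return A list with `mean_diff`, `se`, `p`, `n`.
#' @export
paired_region_difference <- function(target, unaffected) {
  stopifnot(length(target) == length(unaffected))
  n <- length(target)
  if (n < 2L) stop("need at least 2 pairs")
  d <- target - unaffected
  if (stats::sd(d) == 0) {
    warning("zero-variance differences; degenerate paired test")
    return(list(mean_diff = mean(d), se = 0,
                p = if (mean(d) == 0) 1 else 0, n = n))
  }
  tt <- stats::t.test(target, unaffected, paired = TRUE)
  list(mean_diff = unname(tt$estimate), se = unname(tt$stderr),
       p = tt$p.value, n = n)
}
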