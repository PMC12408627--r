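# Brute-force ICC(2,1) oracle from aov() mean squares, independent of the
# package implementation.
icc_oracle <- function(test, retest) {
  n <- length(test); k <- 2
  d <- data.frame(y = c(test, retest),
                  subj = factor(rep(seq_len(n), 2)),
                  sess = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subj + sess, data = d))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

test_that("identical sessions give ICC 1 and zero-width agreement limits", {
  x <- c(3, 7, 9, 14, 21)
  icc <- icc_2_1(x, x)
  expect_equal(icc$icc, 1)
  ba <- bland_altman(x, x)
  expect_equal(unname(ba$loa), c(0, 0))
  ss <- sem_sdd(sd(x), 1)
  expect_equal(ss$sem, 0)
  expect_equal(ss$sdd, 0)
})

test_that("ICC matches the brute-force ANOVA oracle on a worked set", {
  test <- c(1, 3, 5, 7); retest <- c(2, 3, 4, 8)
  got <- icc_2_1(test, retest)
  expect_equal(got$icc, icc_oracle(test, retest), tolerance = 1e-12)
  # and on random data
  set.seed(81)
  for (i in 1:5) {
    a <- rnorm(12, 10, 3); b <- a + rnorm(12, 0, 2)
    expect_equal(icc_2_1(a, b)$icc, icc_oracle(a, b), tolerance = 1e-10)
  }
})

test_that("ICC estimates the variance-components truth at large n", {
  set.seed(82)
  n <- 500
  subj <- rnorm(n, 0, 3)           # sigma_s^2 = 9
  test <- subj + rnorm(n, 0, 1)    # sigma_e^2 = 1
  retest <- subj + rnorm(n, 0, 1)
  out <- icc_2_1(test, retest)
  expect_equal(out$icc, 0.9, tolerance = 0.02 / 0.9)
  expect_lt(out$ci[["lower"]], out$icc)
  expect_gt(out$ci[["upper"]], out$icc)
})

test_that("ICC recovery holds across the reliability spectrum", {
  # mean estimate over replicate cohorts of n = 500: checks estimator bias
  # with Monte-Carlo error well below the 0.03 tolerance
  set.seed(83)
  n <- 500
  for (truth in c(0.2, 0.5, 0.8, 0.95)) {
    sigma_s <- sqrt(truth); sigma_e <- sqrt(1 - truth)
    est <- replicate(10, {
      subj <- rnorm(n, 0, sigma_s)
      icc_2_1(subj + rnorm(n, 0, sigma_e), subj + rnorm(n, 0, sigma_e))$icc
    })
    expect_lt(abs(mean(est) - truth), 0.03)
  }
})

test_that("SEM and SDD follow sd*sqrt(1-ICC) and the 1.96*sqrt(2) multiple", {
  # reference-table arithmetic: SEM 2.02 -> SDD 5.60; SEM 1.96 -> SDD 5.43
  expect_equal(round(sem_sdd(2.02, 0)$sdd, 2), 5.60)
  expect_equal(round(sem_sdd(1.96, 0)$sdd, 2), 5.43)
  set.seed(84)
  for (i in 1:20) {
    ss <- sem_sdd(runif(1, 0, 10), runif(1, -1, 1))
    expect_equal(ss$sdd / max(ss$sem, 1e-300), 1.96 * sqrt(2))
  }
  expect_error(sem_sdd(1, 1.2), "<= 1")
})

test_that("Bland-Altman limits reproduce reference-table arithmetic", {
  expect_equal(round(loa_from_stats(-1.05, 4.17)$loa[["lower"]], 1), -9.2)
  expect_equal(round(loa_from_stats(0.39, 3.56)$loa[["lower"]], 1), -6.6)
  expect_equal(round(loa_from_stats(0.39, 3.56)$loa[["upper"]], 1), 7.4)
  expect_equal(round(loa_from_stats(-0.04, 0.09)$loa[["lower"]], 1), -0.2)
})

test_that("Bland-Altman limits contain about 95% of Gaussian differences", {
  set.seed(85)
  n <- 10000
  test <- rnorm(n, 10, 2)
  retest <- test + rnorm(n, 0.5, 1.5)
  ba <- bland_altman(test, retest)
  d <- retest - test
  cover <- mean(d >= ba$loa[["lower"]] & d <= ba$loa[["upper"]])
  expect_gt(cover, 0.93)
  expect_lt(cover, 0.97)
})

test_that("correlation method choice, values and categories behave", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  out <- correlate(x, 2 * x, force_method = "pearson")
  expect_equal(out$r, 1)
  expect_equal(out$category, "high")
  # skewed data routes to Spearman
  set.seed(86)
  a <- rexp(40)^3
  b <- a + rexp(40)^3
  expect_equal(correlate(a, b)$method, "spearman")
  expect_equal(correlation_category(c(0.1, 0.35, 0.50, 0.73)),
               c("low", "moderate", "substantial", "high"))
  # band edges: 0.30 moderate, 0.45 substantial, 0.60 high
  expect_equal(correlation_category(c(0.30, 0.45, 0.60)),
               c("moderate", "substantial", "high"))
  expect_error(correlate(rep(1, 5), 1:5), "constant")
})

test_that("ICC categories follow the conventional reliability bands", {
  expect_equal(icc_category(c(0.2, 0.40, 0.41, 0.75, 0.76, 0.95)),
               c("poor", "poor", "fair-to-good", "fair-to-good",
                 "good-to-excellent", "good-to-excellent"))
})

test_that("paired region difference reproduces its arithmetic identities", {
  set.seed(87)
  target <- rnorm(14, 15, 6)
  unaffected <- rnorm(14, 8.8, 3.5)
  out <- paired_region_difference(target, unaffected)
  expect_equal(out$mean_diff, mean(target) - mean(unaffected),
               tolerance = 1e-12)
  expect_equal(out$se, sd(target - unaffected) / sqrt(14), tolerance = 1e-12)
  expect_warning(paired_region_difference(target, target), "zero-variance")
  same <- suppressWarnings(paired_region_difference(target, target))
  expect_equal(same$mean_diff, 0)
  expect_equal(same$p, 1)
})
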