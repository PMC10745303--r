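test_that("ICC(1,1) matches its definition and the ANOVA oracle", {
  # two identical columns: perfect reliability
  m <- cbind(1:6, 1:6)
  r <- icc_oneway_single(m)
  expect_identical(r$icc, 1)
  expect_identical(r$category, "excellent")
  expect_identical(r$mdc95, 0)
  # no between-subject variance, only noise: ICC <= 0
  set.seed(1)
  m0 <- matrix(rnorm(20), 10, 2)
  m0 <- m0 - rowMeans(m0) + 5
  expect_lte(icc_oneway_single(m0)$icc, 0)
  expect_identical(icc_oneway_single(m0)$category, "very poor")
  # random matrices against the lm/anova mean-squares oracle
  set.seed(2)
  for (i in 1:20) {
    mm <- matrix(rnorm(12, 10, 2), 6, 2) + rnorm(6, 0, 3)
    expect_equal(icc_oneway_single(mm)$icc, oracle_icc11(mm),
                 tolerance = 1e-10)
  }
  expect_error(icc_oneway_single(matrix(3, 4, 2)), "zero total variance")
  expect_error(icc_oneway_single(matrix(c(1, 2, NA, 4), 2, 2)), "missing")
})

test_that("ICC(2,k) matches its definition and the ANOVA oracle", {
  # three identical raters
  m <- cbind(1:5, 1:5, 1:5)
  expect_identical(icc_twoway_average(m)$icc, 1)
  # rater-specific constant offsets: consistency is perfect, so the
  # average-measure agreement ICC stays high but below 1
  base <- c(3, 8, 15, 24, 40)
  moff <- cbind(base, base + 2, base - 1)
  r <- icc_twoway_average(moff)
  expect_gt(r$icc, 0.9)
  expect_lt(r$icc, 1)
  # suppressed: anova warns about the (intentionally) perfect subject fit
  expect_equal(r$icc, suppressWarnings(oracle_icc2k(moff)),
               tolerance = 1e-10)
  # random matrices against the oracle
  set.seed(3)
  for (i in 1:20) {
    mm <- matrix(rnorm(15, 10, 2), 5, 3) + rnorm(5, 0, 3)
    expect_equal(icc_twoway_average(mm)$icc, oracle_icc2k(mm),
                 tolerance = 1e-10)
  }
})

test_that("ICC confidence intervals match an independent reference", {
  # reference values computed with pingouin.intraclass_corr (Python) on the
  # same matrices, reported there to two decimals
  set.seed(42)
  m2 <- matrix(rnorm(20, 10, 3), 10, 2)
  m2[, 2] <- m2[, 1] * 0.9 + rnorm(10, 0, 1)
  m3 <- matrix(rnorm(30, 10, 3), 10, 3)
  m3[, 2] <- m3[, 1] + rnorm(10, 0.5, 0.8)
  m3[, 3] <- m3[, 1] + rnorm(10, -0.3, 0.8)
  r1 <- icc_oneway_single(m2)
  expect_equal(r1$icc, 0.8212997923052558, tolerance = 1e-12)
  expect_equal(round(c(r1$ci_low, r1$ci_high), 2), c(0.46, 0.95))
  r2 <- icc_twoway_average(m3)
  expect_equal(r2$icc, 0.9780693411, tolerance = 1e-9)
  expect_equal(round(c(r2$ci_low, r2$ci_high), 2), c(0.81, 1.00))
  # interval brackets the estimate
  expect_true(r1$ci_low <= r1$icc && r1$icc <= r1$ci_high)
  expect_true(r2$ci_low <= r2$icc && r2$icc <= r2$ci_high)
})

test_that("adding within-cell noise never raises expected ICC", {
  mean_icc <- function(noise_sd) {
    mean(vapply(1:30, function(s) {
      set.seed(1000 + s)
      subj <- rnorm(10, 10, 3)
      m <- cbind(subj, subj) + matrix(rnorm(20, 0, noise_sd), 10, 2)
      icc_oneway_single(m)$icc
    }, numeric(1)))
  }
  iccs <- vapply(c(0.5, 1.5, 4), mean_icc, numeric(1))
  expect_true(all(diff(iccs) < 0))
})

test_that("MDC95 and MDC% behave as defined", {
  d <- c(-2, 0, 2)                     # sd = 2
  expect_equal(mdc95(d), 3.92)
  expect_equal(mdc95(rep(1.7, 4)), 0)   # all differences equal
  expect_error(mdc95(1), ">= 2")
  expect_equal(1.96 * 0.211, 0.41356)
  expect_identical(mdc_percent(0), 0)
  expect_error(mdc_percent(-0.1), "sdd")
  expect_error(mdc_percent(0.4, "rating"), "slope_b")
  # strictly increasing in sdd and bounded in [0, 100)
  v <- vapply(seq(0, 2, by = 0.1), mdc_percent, numeric(1))
  expect_true(all(diff(v) > 0))
  expect_true(all(v >= 0 & v < 100))
})

test_that("Spearman rho matches rank-Pearson oracle, symmetry and monotone invariance", {
  expect_identical(spearman_rho(1:8, (1:8)^3)$rho, 1)
  expect_identical(spearman_rho(1:8, -(1:8))$rho, -1)
  # ties: equals rank-then-Pearson computed via base R
  set.seed(4)
  for (i in 1:20) {
    x <- sample(1:5, 8, TRUE); y <- sample(1:5, 8, TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(spearman_rho(x, y)$rho, cor(rank(x), rank(y)),
                 tolerance = 1e-12)
    expect_identical(spearman_rho(x, y)$rho, spearman_rho(y, x)$rho)
    # invariant under strictly monotone transforms
    expect_equal(spearman_rho(exp(x), y)$rho, spearman_rho(x, y)$rho,
                 tolerance = 1e-12)
  }
  # exact permutation p agrees with base R for untied small samples
  x <- 1:5; y <- c(2, 1, 4, 3, 5)
  expect_equal(spearman_rho(x, y, p_method = "exact")$p_value,
               cor.test(x, y, method = "spearman")$p.value,
               tolerance = 1e-12)
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})

test_that("Wilcoxon signed-rank exact p equals full enumeration", {
  # six positive differences: two-sided p = 2/64
  expect_identical(wilcoxon_signed_rank(rep(0, 6), 1:6)$p_value, 0.03125)
  # perfectly antisymmetric differences
  expect_identical(
    wilcoxon_signed_rank(rep(0, 6), c(1, -1, 2, -2, 3, -3))$p_value, 1)
  # agreement with base R's exact test when there are no ties or zeros
  set.seed(5)
  d <- rnorm(12)
  expect_equal(wilcoxon_signed_rank(rep(0, 12), d)$p_value,
               wilcox.test(d, exact = TRUE)$p.value, tolerance = 1e-12)
  # enumeration oracle, including ties, across random small cases
  set.seed(6)
  for (i in 1:15) {
    n <- sample(4:12, 1)
    d <- sample(c(-4, -3, -2, -1, 1, 2, 3, 4), n, TRUE)
    p <- wilcoxon_signed_rank(rep(0, n), d)$p_value
    expect_equal(p, oracle_wilcoxon_p(d), tolerance = 1e-12)
    expect_true(p > 0 && p <= 1)
  }
  # zeros are dropped before ranking
  wz <- wilcoxon_signed_rank(c(1, 2, 3, 4), c(1, 5, 6, 7))
  expect_identical(wz$n_zero_dropped, 1L)
  expect_identical(wz$n_effective, 3L)
  expect_error(wilcoxon_signed_rank(1:4, 1:4), "zero")
  # large-sample normal approximation stays close to the exact value
  set.seed(7)
  d30 <- rnorm(30, 0.3)
  pn <- wilcoxon_signed_rank(rep(0, 30), d30)$p_value
  pe <- wilcoxon_signed_rank(rep(0, 30), d30, exact_max_n = 30)$p_value
  expect_equal(pn, pe, tolerance = 0.05)
})

test_that("Weber-Fechner fit recovers the generating line", {
  # exact log-linear data
  rating <- rep(0:4, each = 3)
  amp <- 10^(0.8 + 0.5 * rating)
  fit <- suppressWarnings(fit_weber_fechner(rating, amp))  # exact fit warns
  expect_equal(unname(coef(fit)), c(0.8, 0.5), tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_equal(predict(fit, 2), 10^1.8, tolerance = 1e-9)
  expect_error(fit_weber_fechner(rep(2, 10), 10^rnorm(10)), "distinct")
  expect_error(fit_weber_fechner(0:4, c(1, 2, -3, 4, 5)), "positive")
  # simulated cohorts: true slope inside the 95% CI in most seeds
  # wide half-step rating range so scale clipping and rating discretization
  # (both of which attenuate a regression on a noisy regressor) stay well
  # inside the interval width
  wf <- weber_fechner_spec(intercept_a = 1, slope_b = 0.15,
                           rating_noise_sd = 0.1, rating_min = -10,
                           rating_max = 12, rating_step = 0.5)
  hits <- vapply(1:50, function(s) {
    co <- generate_cohort(cohort_spec(n_patients = 40, weber_fechner = wf,
                                      seed = 5000 + s))
    f <- fit_weber_fechner(co$rating_pre, co$amplitude_pre)
    ci <- confint(f)["slope_b", ]
    ci[1] <= 0.15 && 0.15 <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
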