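# Reliability and clinical-association statistics, implemented from the
# ANOVA mean squares up so that every quantity is auditable against an
# independent variance-components computation.

icc_category <- function(icc) {
  if (icc >= 0.90) "excellent"
  else if (icc >= 0.70) "good"
  else if (icc >= 0.50) "moderate"
  else if (icc >= 0.30) "poor"
  else "very poor"
}

check_measurement_matrix <- function(m) {
  m <- as.matrix(m)
  check_that(is.numeric(m), "measurement matrix must be numeric")
  check_that(nrow(m) >= 2L && ncol(m) >= 2L,
             "need >= 2 subjects and >= 2 columns")
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop(sprintf("measurement matrix has missing cells (first: subject %d, column %d)",
                 bad[1L, 1L], bad[1L, 2L]), call. = FALSE)
  }
  m
}

# One-way / two-way random-effects ANOVA mean squares of an n x k matrix.
anova_mean_squares <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  rm_ <- rowMeans(m); cm_ <- colMeans(m)
  ssb <- k * sum((rm_ - grand)^2)
  ssj <- n * sum((cm_ - grand)^2)
  sst <- sum((m - grand)^2)
  ssw <- sum((m - rm_)^2)
  sse <- sst - ssb - ssj
  list(n = n, k = k,
       bms = ssb / (n - 1),
       wms = ssw / (n * (k - 1)),
       jms = ssj / (k - 1),
       ems = sse / ((n - 1) * (k - 1)),
       sst = sst)
}

new_reliability_result <- function(icc, ci, type, ms, sdd, conf_level) {
  structure(list(icc = icc, ci_low = ci[1L], ci_high = ci[2L], type = type,
                 n = ms$n, k = ms$k, sdd = sdd,
                 mdc95 = if (is.na(sdd)) NA_real_ else 1.96 * sdd,
                 category = icc_category(icc), conf_level = conf_level),
            class = "reliability_result")
}

#' One-way random-effects single-measure ICC, ICC(1,1)
#'
#' Test-retest reliability: each subject is measured on `k` occasions that
#' are not distinguishable columns (occasion is nested in subject). From the
#' one-way ANOVA mean squares,
#' `ICC(1,1) = (BMS - WMS) / (BMS + (k - 1) WMS)`, with the 95% confidence
#' interval from the F distribution (Shrout-Fleiss construction). Negative
#' estimates are reported as computed. For two-column (test-retest)
#' matrices the SD of the paired differences and MDC95 = 1.96 x SDd are
#' attached.
#'
#' @param m subjects x occasions numeric matrix (no missing cells).
#' @param conf_level confidence level for the interval.
#' @return an object of class `reliability_result`: `icc`, `ci_low`,
#'   `ci_high`, `sdd`, `mdc95`, `category` ("excellent" >= 0.90, "good"
#'   >= 0.70, "moderate" >= 0.50, "poor" >= 0.30, else "very poor").
#' @export
icc_oneway_single <- function(m, conf_level = 0.95) {
  m <- check_measurement_matrix(m)
  ms <- anova_mean_squares(m)
  check_that(ms$sst > 0, "ICC undefined: zero total variance")
  n <- ms$n; k <- ms$k
  icc <- (ms$bms - ms$wms) / (ms$bms + (k - 1) * ms$wms)
  alpha <- 1 - conf_level
  if (ms$wms <= 0) {
    ci <- c(1, 1)   # identical columns: no within-subject variance
  } else {
    f_obs <- ms$bms / ms$wms
    fl <- f_obs / qf(1 - alpha / 2, n - 1, n * (k - 1))
    fu <- f_obs * qf(1 - alpha / 2, n * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  }
  sdd <- if (k == 2L) sd(m[, 2L] - m[, 1L]) else NA_real_
  new_reliability_result(icc, ci, "ICC(1,1)", ms, sdd, conf_level)
}

#' Two-way random-effects average-measure ICC, ICC(2,k)
#'
#' Inter-rater reliability of the mean of `k` raters, raters treated as a
#' random sample: `ICC(2,k) = (BMS - EMS) / (BMS + (JMS - EMS) / n)` from
#' the two-way ANOVA mean squares. The confidence interval is computed for
#' the single-measure ICC(2,1) via the Shrout-Fleiss F interval (with its
#' Satterthwaite degrees of freedom) and stepped up to the average measure
#' with the Spearman-Brown relation.
#'
#' @inheritParams icc_oneway_single
#' @return an object of class `reliability_result`.
#' @export
icc_twoway_average <- function(m, conf_level = 0.95) {
  m <- check_measurement_matrix(m)
  ms <- anova_mean_squares(m)
  check_that(ms$sst > 0, "ICC undefined: zero total variance")
  n <- ms$n; k <- ms$k
  icc_k <- (ms$bms - ms$ems) / (ms$bms + (ms$jms - ms$ems) / n)
  alpha <- 1 - conf_level
  if (ms$ems <= 0 && ms$jms <= 0) {
    ci <- c(1, 1)
  } else {
    icc1 <- (ms$bms - ms$ems) /
      (ms$bms + (k - 1) * ms$ems + k * (ms$jms - ms$ems) / n)
    fj <- ms$jms / ms$ems
    vn <- (k - 1) * (n - 1) *
      (k * icc1 * fj + n * (1 + (k - 1) * icc1) - k * icc1)^2
    vd <- (n - 1) * k^2 * icc1^2 * fj^2 +
      (n * (1 + (k - 1) * icc1) - k * icc1)^2
    v <- vn / vd
    f1 <- qf(1 - alpha / 2, n - 1, v)
    f2 <- qf(1 - alpha / 2, v, n - 1)
    low1 <- n * (ms$bms - f1 * ms$ems) /
      (f1 * (k * ms$jms + (k * n - k - n) * ms$ems) + n * ms$bms)
    up1 <- n * (f2 * ms$bms - ms$ems) /
      (k * ms$jms + (k * n - k - n) * ms$ems + n * f2 * ms$bms)
    sb <- function(r) k * r / (1 + (k - 1) * r)
    ci <- c(sb(low1), sb(up1))
  }
  sdd <- if (k == 2L) sd(m[, 2L] - m[, 1L]) else NA_real_
  new_reliability_result(icc_k, ci, sprintf("ICC(2,%d)", k), ms, sdd,
                         conf_level)
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("%s = %.3f (%d%% CI %.3f-%.3f), %s reliability [n=%d, k=%d]\n",
              x$type, x$icc, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$category, x$n, x$k))
  if (!is.na(x$sdd)) {
    cat(sprintf("  SDd = %.4g, MDC95 = %.4g\n", x$sdd, x$mdc95))
  }
  invisible(x)
}

#' Minimal detectable change at 95% confidence
#'
#' `MDC95 = 1.96 x SDd`, where SDd is the standard deviation of the paired
#' test-retest differences.
#'
#' @param differences paired test-retest differences (length >= 2).
#' @return MDC95 in the units of the measure.
#' @examples
#' mdc95(c(-2, 0, 2))  # 1.96 * sd = 3.92
#' @export
mdc95 <- function(differences) {
  check_that(is.numeric(differences) && length(differences) >= 2L &&
               all(is.finite(differences)),
             "need >= 2 finite paired differences")
  1.96 * sd(differences)
}

#' Minimal detectable change as a percentage of baseline
#'
#' For a log10-transformed measure, a change is detectable when it exceeds
#' MDC95 = 1.96 x SDd log units, i.e. when the measure falls below
#' `10^(-1.96 SDd)` of baseline; the just-detectable percent reduction is
#' `MDC% = 100 (1 - 10^(-1.96 SDd))`. For a clinical rating scale the
#' rating change is first converted to log10 amplitude through the
#' Weber-Fechner slope `b` (log10-mm per rating point):
#' `MDC% = 100 (1 - 10^(-b x 1.96 SDd))`.
#'
#' @param sdd SD of test-retest differences (log10 units, or rating points
#'   when `scale = "rating"`); must be >= 0.
#' @param scale `"log10"` for log-transformed measures, `"rating"` for
#'   rating scales.
#' @param slope_b Weber-Fechner slope, required when `scale = "rating"`.
#' @return MDC% in percent of baseline, in `[0, 100)`.
#' @examples
#' mdc_percent(0.211)                              # ~61 (video amplitude)
#' mdc_percent(0.408, "rating", slope_b = 1)       # ~84 (TETRAS)
#' @export
mdc_percent <- function(sdd, scale = c("log10", "rating"), slope_b = NULL) {
  scale <- match.arg(scale)
  check_scalar(sdd, "sdd", min = 0)
  if (scale == "rating") {
    check_that(!is.null(slope_b), "slope_b required for rating-scale MDC%%")
    check_scalar(slope_b, "slope_b", min = 0, strict_min = TRUE)
  } else {
    slope_b <- 1
  }
  100 * (1 - 10^(-slope_b * 1.96 * sdd))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks). The
#' p-value uses the t approximation
#' `t = rho sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom, or
#' exact enumeration of all permutations for small samples
#' (`p_method = "exact"`, n <= 9).
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @param p_method `"t"` or `"exact"`.
#' @return list with `rho`, `p_value`, `n`, `method`.
#' @export
spearman_rho <- function(x, y, p_method = c("t", "exact")) {
  p_method <- match.arg(p_method)
  n <- length(x)
  check_that(length(y) == n && n >= 3L, "need equal-length vectors, n >= 3")
  check_that(all(is.finite(x)) && all(is.finite(y)), "inputs must be finite")
  check_that(length(unique(x)) > 1L && length(unique(y)) > 1L,
             "correlation undefined for a constant input")
  rx <- rank(x); ry <- rank(y)
  rho <- rank_pearson(rx, ry)
  if (p_method == "exact") {
    check_that(n <= 9L, "exact Spearman p limited to n <= 9")
    pm <- permutations(n)
    obs <- abs(rho) - 1e-12
    cnt <- 0L
    for (i in seq_len(nrow(pm))) {
      if (abs(rank_pearson(rx, ry[pm[i, ]])) >= obs) cnt <- cnt + 1L
    }
    p <- cnt / nrow(pm)
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = min(1, p), n = n, method = p_method)
}

rank_pearson <- function(rx, ry) {
  cx <- rx - mean(rx); cy <- ry - mean(ry)
  sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
}

permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Differences `post - pre` are formed, zero differences are dropped
#' (Wilcoxon convention), tied absolute differences receive mid-ranks, and
#' the statistic is the sum of ranks of positive differences. The two-sided
#' p-value is exact -- computed from the full null distribution of the rank
#' sum over all `2^n` sign assignments (via dynamic programming, so ties
#' are handled exactly) -- for `n <= exact_max_n`, and otherwise uses the
#' normal approximation with tie correction and continuity correction.
#' Two-sided exact p is `min(1, 2 min(P(W <= w), P(W >= w)))`.
#'
#' @param pre,post paired measurements of equal length.
#' @param exact_max_n largest effective n for which the exact distribution
#'   is enumerated.
#' @return list with `statistic` (W+, rank sum of positive differences),
#'   `p_value`, `n_effective`, `n_zero_dropped`, `method`.
#' @export
wilcoxon_signed_rank <- function(pre, post, exact_max_n = 25L) {
  check_that(length(pre) == length(post) && length(pre) >= 1L,
             "need equal-length paired samples")
  d <- post - pre
  check_that(all(is.finite(d)), "differences must be finite")
  nz <- d != 0
  check_that(any(nz), "all paired differences are zero")
  d <- d[nz]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max_n) {
    r2 <- as.integer(round(2 * r))        # mid-ranks live on a half-integer grid
    total <- sum(r2)
    f <- numeric(total + 1L); f[1L] <- 1
    for (wi in r2) {
      shifted <- c(numeric(wi), f[seq_len(total + 1L - wi)])
      f <- f + shifted
    }
    f <- f / sum(f)
    w2 <- as.integer(round(2 * w))
    ple <- sum(f[seq_len(w2 + 1L)])
    pge <- sum(f[(w2 + 1L):(total + 1L)])
    p <- min(1, 2 * min(ple, pge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = w, p_value = p, n_effective = n,
       n_zero_dropped = sum(!nz), method = method)
}

#' Fit the Weber-Fechner rating-amplitude relation
#'
#' Least-squares fit of log10 tremor amplitude on the clinical rating:
#' `log10(amplitude mm) = a + b rating`. The slope `b` converts a rating
#' change into a fold change of amplitude (one rating point = `10^b`-fold),
#' which is what links rating-scale MDC to percent amplitude change.
#'
#' @param rating clinical scores (>= 3 distinct values).
#' @param amplitude_mm videographic amplitudes, mm (> 0).
#' @return an object of class `weber_fechner_fit` with `intercept_a`,
#'   `slope_b`, `r_squared` and the underlying `lm` fit; supports `coef`,
#'   `predict` (rating to amplitude), `confint`, `print`, `plot`.
#' @export
fit_weber_fechner <- function(rating, amplitude_mm) {
  n <- length(rating)
  check_that(length(amplitude_mm) == n && n >= 3L,
             "need equal-length rating and amplitude vectors, n >= 3")
  check_that(all(is.finite(amplitude_mm)) && all(amplitude_mm > 0),
             "amplitudes must be positive")
  check_that(length(unique(rating)) >= 3L,
             "need >= 3 distinct rating values")
  df <- data.frame(rating = as.numeric(rating),
                   log_amplitude = log10(amplitude_mm))
  fit <- lm(log_amplitude ~ rating, data = df)
  structure(list(intercept_a = unname(coef(fit)[1L]),
                 slope_b = unname(coef(fit)[2L]),
                 r_squared = summary(fit)$r.squared,
                 lm = fit, n = n),
            class = "weber_fechner_fit")
}

#' @export
coef.weber_fechner_fit <- function(object, ...) {
  c(intercept_a = object$intercept_a, slope_b = object$slope_b)
}

#' @export
confint.weber_fechner_fit <- function(object, parm, level = 0.95, ...) {
  ci <- confint(object$lm, level = level)
  rownames(ci) <- c("intercept_a", "slope_b")
  ci
}

#' @param rating ratings to predict at.
#' @param response `"amplitude"` (mm) or `"log10_amplitude"`.
#' @rdname fit_weber_fechner
#' @export
predict.weber_fechner_fit <- function(object, rating,
                                      response = c("amplitude",
                                                   "log10_amplitude"), ...) {
  response <- match.arg(response)
  la <- object$intercept_a + object$slope_b * rating
  if (response == "amplitude") 10^la else la
}

#' @export
print.weber_fechner_fit <- function(x, ...) {
  cat(sprintf("Weber-Fechner fit: log10(amplitude mm) = %.3f + %.3f * rating\n",
              x$intercept_a, x$slope_b))
  cat(sprintf("  one rating point = %.2f-fold amplitude; R^2 = %.3f (n = %d)\n",
              10^x$slope_b, x$r_squared, x$n))
  invisible(x)
}

#' @export
plot.weber_fechner_fit <- function(x, ...) {
  df <- x$lm$model
  plot(df$rating, df$log_amplitude, xlab = "clinical rating",
       ylab = "log10 amplitude [log10 mm]", ...)
  abline(x$intercept_a, x$slope_b, col = 2)
  invisible(x)
}
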