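# Independent oracles used across the suite. Each recomputes the target
# quantity by a different route than the package implementation.

# ICC(1,1) from one-way ANOVA mean squares obtained via lm/anova.
oracle_icc11 <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   subject = factor(rep(seq_len(n), k)))
  a <- stats::anova(stats::lm(y ~ subject, data = df))
  bms <- a["subject", "Mean Sq"]; wms <- a["Residuals", "Mean Sq"]
  (bms - wms) / (bms + (k - 1) * wms)
}

# ICC(2,k) from two-way ANOVA mean squares obtained via lm/anova.
oracle_icc2k <- function(m) {
  n <- nrow(m); k <- ncol(m)
  df <- data.frame(y = as.vector(m),
                   subject = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  a <- stats::anova(stats::lm(y ~ subject + rater, data = df))
  bms <- a["subject", "Mean Sq"]
  jms <- a["rater", "Mean Sq"]
  ems <- a["Residuals", "Mean Sq"]
  (bms - ems) / (bms + (jms - ems) / n)
}

# Exact two-sided Wilcoxon signed-rank p by brute-force enumeration of all
# 2^n sign assignments (feasible for n <= 12), mid-ranks for ties.
oracle_wilcoxon_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  w_all <- apply(signs, 1L, function(s) sum(r[s]))
  min(1, 2 * min(mean(w_all <= w_obs + 1e-9), mean(w_all >= w_obs - 1e-9)))
}

# Population (large-n) Spearman correlation between log10 amplitude
# X ~ N(mu, sigma^2) and the rating R = clip(round((X - a)/b + eps)) of the
# Weber-Fechner generator, by numerical integration of the grade
# correlation (mid-rank convention for the discrete margin).
oracle_population_spearman <- function(mu, sigma, a, b, noise_sd,
                                       rmin, rmax, step = 1) {
  xs <- seq(mu - 6 * sigma, mu + 6 * sigma, length.out = 4001)
  w <- stats::dnorm(xs, mu, sigma); w <- w / sum(w)
  Fx <- stats::pnorm(xs, mu, sigma)
  rvals <- seq(rmin, rmax, by = step)
  z <- (xs - a) / b
  P <- sapply(rvals, function(r) {
    lo <- (r - step / 2 - z) / noise_sd
    hi <- (r + step / 2 - z) / noise_sd
    p <- stats::pnorm(hi) - stats::pnorm(lo)
    if (r == rmin) p <- stats::pnorm(hi)
    if (r == rmax) p <- 1 - stats::pnorm(lo)
    p
  })
  pr <- colSums(w * P)
  G <- cumsum(pr) - pr / 2
  EFG <- sum(w * Fx * (P %*% G))
  varG <- sum(pr * G^2) - sum(pr * G)^2
  varF <- sum(w * Fx^2) - sum(w * Fx)^2
  (EFG - sum(w * Fx) * sum(pr * G)) / sqrt(varF * varG)
}

# Arc length of a parametric curve by dense polyline quadrature.
oracle_arc_length <- function(position_fun, t0, t1, n = 50000L) {
  ts <- seq(t0, t1, length.out = n)
  P <- position_fun(ts)
  sum(sqrt(diff(P[, 1L])^2 + diff(P[, 2L])^2))
}

# Build a trajectory directly from coordinate vectors (mm) for unit tests.
make_traj <- function(x, y, fps = 25) trajectory_series(x, y, fps = fps)
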