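# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` with a temporarily seeded RNG, restoring the caller's
# random state afterwards so generators never perturb user simulations.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  code
}

check_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

check_scalar <- function(x, field, min = -Inf, max = Inf,
                         strict_min = FALSE, strict_max = FALSE) {
  check_that(is.numeric(x) && length(x) == 1L && is.finite(x),
             "invalid '%s': must be a finite numeric scalar", field)
  lo_ok <- if (strict_min) x > min else x >= min
  hi_ok <- if (strict_max) x < max else x <= max
  check_that(lo_ok && hi_ok, "invalid '%s': %g outside allowed range", field, x)
  invisible(x)
}

geomean <- function(x) exp(mean(log(x)))

# Centered local-linear baseline over a sliding window of `window` seconds.
# Equivalent to a centered moving average for linear trends in the interior,
# but unbiased at the record edges where the window becomes asymmetric.
local_linear_baseline <- function(y, t, window) {
  n <- length(y)
  if (n < 3L) return(rep(mean(y), n))
  dt <- t[2L] - t[1L]
  k <- max(1L, as.integer(round(window / dt / 2)))
  idx <- seq_len(n)
  lo <- pmax(1L, idx - k)
  hi <- pmin(n, idx + k)
  tc <- t - t[1L]          # guard against cancellation for long records
  c0 <- c(0, cumsum(rep(1, n)))
  c1 <- c(0, cumsum(tc))
  c2 <- c(0, cumsum(tc * tc))
  cy <- c(0, cumsum(y))
  cty <- c(0, cumsum(tc * y))
  m <- c0[hi + 1L] - c0[lo]
  S1 <- c1[hi + 1L] - c1[lo]
  S2 <- c2[hi + 1L] - c2[lo]
  Sy <- cy[hi + 1L] - cy[lo]
  Sty <- cty[hi + 1L] - cty[lo]
  det <- m * S2 - S1^2
  beta <- ifelse(det > .Machine$double.eps * S2 * m, (m * Sty - S1 * Sy) / det, 0)
  alpha <- (Sy - beta * S1) / m
  alpha + beta * tc
}

# Sliding peak-to-peak envelope (window in seconds, centered).
rolling_ptp <- function(s, t, window) {
  n <- length(s)
  dt <- t[2L] - t[1L]
  k <- max(1L, as.integer(round(window / dt / 2)))
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1L, i - k):min(n, i + k)
    out[i] <- max(s[j]) - min(s[j])
  }
  out
}

# Linear-interpolation weight matrix mapping `nin` regularly spaced samples
# onto `nout` positions spanning the same interval (used to upscale the
# coarse background texture grid to full frame resolution).
interp_matrix <- function(nout, nin) {
  pos <- seq(1, nin, length.out = nout)
  lo <- pmin(floor(pos), nin - 1L)
  w <- pos - lo
  M <- matrix(0, nout, nin)
  M[cbind(seq_len(nout), lo)] <- 1 - w
  M[cbind(seq_len(nout), lo + 1L)] <- w
  M
}
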