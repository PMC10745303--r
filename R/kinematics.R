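#' Analysis configuration defaults
#'
#' Collects the tunable parameters of the kinematic analysis in one list.
#'
#' @param window_length length of the postural analysis window, s.
#' @param search_start,search_end time range (s) searched for the
#'   highest-amplitude window centre.
#' @param envelope_window sliding window (s) of the peak-to-peak envelope
#'   used to locate the highest-amplitude moment.
#' @param detrend_window centered baseline-removal window, s.
#' @param amplitude_floor amplitude (mm) below which oscillation is treated
#'   as "no tremor"; also floors the cycle-detection hysteresis.
#' @param hysteresis_mult multiplier on the noise SD for the zero-crossing
#'   hysteresis band.
#' @param hysteresis_cap cap on the hysteresis band as a fraction of the
#'   robust signal half peak-to-peak.
#' @param amplitude_method `"sine_fit"` (per-cycle local sinusoid
#'   least-squares; robust to coarse 25 fps sampling) or `"sample_ptp"`
#'   (raw max - min of the samples in each cycle).
#' @param speed_threshold,speed_sustain drawing-span detection: motion is
#'   "sustained" when speed exceeds `speed_threshold` mm/s for at least
#'   `speed_sustain` s.
#' @return a named list of class `tremor_config`.
#' @export
tremor_config <- function(window_length = 10, search_start = 5,
                          search_end = 55, envelope_window = 1,
                          detrend_window = 1, amplitude_floor = 0.5,
                          hysteresis_mult = 3, hysteresis_cap = 0.25,
                          amplitude_method = c("sine_fit", "sample_ptp"),
                          speed_threshold = 5, speed_sustain = 0.2) {
  structure(list(window_length = window_length, search_start = search_start,
                 search_end = search_end, envelope_window = envelope_window,
                 detrend_window = detrend_window,
                 amplitude_floor = amplitude_floor,
                 hysteresis_mult = hysteresis_mult,
                 hysteresis_cap = hysteresis_cap,
                 amplitude_method = match.arg(amplitude_method),
                 speed_threshold = speed_threshold,
                 speed_sustain = speed_sustain),
            class = "tremor_config")
}

#' Frame-to-frame displacement, velocity and acceleration
#'
#' Implements the finite-difference kinematics used for videographic tremor
#' parameters: between consecutive frames,
#' `displacement = sqrt(dx^2 + dy^2)` (mm),
#' `velocity = displacement / dt` (mm/s), and
#' `acceleration = (V1 - V0) / dt` (mm/s^2), with `dt = 1/fps`.
#'
#' @param traj a calibrated [trajectory_series()] in mm (or px with a
#'   mm_per_px scale attached, converted internally); length >= 3.
#' @return an object of class `kinematic_series`: list with `displacement`
#'   (length n-1), `velocity` (n-1), `acceleration` (n-2) and `fps`.
#' @examples
#' tr <- trajectory_series(c(0, 3), c(0, 4), fps = 25)
#' k <- compute_kinematics(trajectory_series(c(0, 3, 3), c(0, 4, 4), 25))
#' k$displacement[1]  # 5 mm
#' k$velocity[1]      # 125 mm/s
#' @export
compute_kinematics <- function(traj) {
  stopifnot(inherits(traj, "trajectory_series"))
  traj <- as_mm(traj)
  check_that(nrow(traj) >= 3L, "need >= 3 samples for acceleration")
  fps <- traj_fps(traj)
  disp <- sqrt(diff(traj$x)^2 + diff(traj$y)^2)
  vel <- disp * fps
  acc <- diff(vel) * fps
  structure(list(displacement = disp, velocity = vel, acceleration = acc,
                 fps = fps),
            class = "kinematic_series")
}

#' Scalar tremor signal of a trajectory
#'
#' Reduces the XY path to the one-dimensional oscillation that frequency and
#' amplitude are defined on: a centered local-linear baseline (window
#' `detrend_window` s) is removed from each coordinate, the dominant
#' oscillation axis is taken as the first principal direction of the
#' high-pass component, and both the detrended and the raw (baseline-kept)
#' projections onto that axis are returned. The detrended projection is the
#' tremor signal proper (zero mean); the raw projection is kept as attribute
#' `"raw"` because per-cycle amplitude fitting removes its local trend
#' itself and thereby avoids the slight passband attenuation of the
#' baseline filter.
#'
#' @param traj a calibrated [trajectory_series()].
#' @param detrend_window baseline window, s.
#' @return numeric vector (class `tremor_signal`) with attributes `time`,
#'   `fps`, `axis` (unit vector) and `raw`.
#' @export
tremor_signal <- function(traj, detrend_window = 1) {
  stopifnot(inherits(traj, "trajectory_series"))
  traj <- as_mm(traj)
  check_that(nrow(traj) >= traj_fps(traj),
             "trajectory shorter than one second")
  tt <- traj$time
  X <- cbind(traj$x, traj$y)
  B <- cbind(local_linear_baseline(X[, 1L], tt, detrend_window),
             local_linear_baseline(X[, 2L], tt, detrend_window))
  hp <- X - B
  cv <- crossprod(hp) / nrow(hp)
  if (sum(diag(cv)) < .Machine$double.eps * 100) {
    axis <- c(1, 0)                     # constant trajectory: zero signal
  } else {
    e <- eigen(cv, symmetric = TRUE)
    axis <- e$vectors[, 1L]
    flip <- if (abs(axis[1L]) >= abs(axis[2L])) axis[1L] < 0 else axis[2L] < 0
    if (flip) axis <- -axis
  }
  det_proj <- as.numeric(hp %*% axis)
  det_proj <- det_proj - mean(det_proj)
  raw_proj <- as.numeric(X %*% axis)
  raw_proj <- raw_proj - mean(raw_proj)
  structure(det_proj, time = tt, fps = traj_fps(traj), axis = axis,
            raw = raw_proj, class = "tremor_signal")
}

#' Select the 10 s highest-amplitude analysis window
#'
#' Applies the postural-task window rule: within the search range
#' (default the 5th to 55th second of a 60 s recording) find the moment of
#' highest tremor amplitude -- the maximum of the sliding peak-to-peak
#' envelope of the tremor signal -- and centre a `window_length` (default
#' 10 s) window on it. Ties are broken in favour of the earliest centre, so
#' a constant-amplitude recording yields the earliest admissible window.
#'
#' @param traj a calibrated [trajectory_series()].
#' @param window_length window length, s.
#' @param search_start,search_end admissible window-centre range, s.
#' @param envelope_window sliding peak-to-peak window, s.
#' @param detrend_window baseline window for the tremor signal, s.
#' @return an object of class `analysis_window`: list with `start`, `end`,
#'   `center` (s) and `idx`, the sample indices of the window (always
#'   exactly `window_length * fps + 1` of them).
#' @export
select_analysis_window <- function(traj, window_length = 10,
                                   search_start = 5, search_end = 55,
                                   envelope_window = 1, detrend_window = 1) {
  stopifnot(inherits(traj, "trajectory_series"))
  check_that(search_start <= search_end,
             "invalid search range: search_start > search_end")
  dur <- traj_duration(traj)
  need <- search_end + window_length / 2
  check_that(search_start - window_length / 2 >= -1e-9,
             "search_start must be at least window_length/2")
  check_that(dur + 1e-9 >= need,
             "recording too short for the window rule: need at least %.1f s, have %.1f s",
             need, dur)
  sig <- tremor_signal(traj, detrend_window)
  tt <- attr(sig, "time") - traj$time[1L]
  env <- rolling_ptp(as.numeric(sig), tt, envelope_window)
  cand <- which(tt >= search_start - 1e-9 & tt <= search_end + 1e-9)
  # earliest centre among (numerical) ties for the highest envelope
  e_max <- max(env[cand])
  i_best <- cand[which(env[cand] >= e_max - 1e-9 * abs(e_max))[1L]]
  center <- tt[i_best]
  start <- center - window_length / 2
  end <- center + window_length / 2
  idx <- which(tt >= start - 1e-9 & tt <= end + 1e-9)
  structure(list(start = start, end = end, center = center,
                 window_length = window_length,
                 search_start = search_start, search_end = search_end,
                 idx = idx),
            class = "analysis_window")
}

#' @export
print.analysis_window <- function(x, ...) {
  cat(sprintf("<analysis_window> [%.2f, %.2f] s (centre %.2f s, %d samples)\n",
              x$start, x$end, x$center, length(x$idx)))
  invisible(x)
}

# Hysteresis band for cycle detection: noise-scaled but capped by a fraction
# of the robust signal half peak-to-peak so genuine near-Nyquist tremor is
# never suppressed, and floored at half the no-tremor amplitude floor.
hysteresis_band <- function(s, amplitude_floor = 0.5, mult = 3, cap = 0.25) {
  sigma_d <- 1.4826 * median(abs(diff(s))) / sqrt(2)
  a_rob <- (quantile(s, 0.98, names = FALSE) -
              quantile(s, 0.02, names = FALSE)) / 2
  h <- max(min(mult * sigma_d, cap * a_rob), amplitude_floor / 2)
  list(h = h, a_rob = a_rob)
}

# Schmitt-trigger positive-going zero-crossing detector. An event is
# recorded when the signal rises above +h after having been below -h; the
# event time is the linearly interpolated zero crossing. Returns event times.
schmitt_crossings <- function(s, tt, h) {
  state <- 0L   # 0 unknown, 1 high, -1 low
  events <- numeric(0)
  last_neg <- NA_integer_
  for (i in seq_along(s)) {
    if (s[i] <= 0) last_neg <- i
    if (s[i] >= h) {
      if (state == -1L && !is.na(last_neg) && last_neg < i) {
        j <- last_neg
        tz <- tt[j] + (tt[j + 1L] - tt[j]) * (0 - s[j]) / (s[j + 1L] - s[j])
        events <- c(events, tz)
      }
      state <- 1L
    } else if (s[i] <= -h) {
      state <- -1L
    }
  }
  events
}

#' Tremor frequency as average waves per second
#'
#' Counts complete tremor cycles as positive-going zero crossings of the
#' detrended tremor signal, with a hysteresis band derived from the noise
#' floor to suppress chatter, and reports the average number of waves per
#' second measured over whole cycles:
#' `frequency = n_cycles / (time of last crossing - time of first crossing)`.
#' A signal whose robust amplitude falls below `amplitude_floor` is flagged
#' `no_tremor` and reported as 0 Hz.
#'
#' @param signal a [tremor_signal()] or plain numeric vector.
#' @param time sample times, s (taken from the signal attributes when
#'   absent).
#' @param amplitude_floor no-tremor amplitude threshold, mm.
#' @param hysteresis optional explicit hysteresis band, mm (overrides the
#'   automatic choice).
#' @param hysteresis_mult,hysteresis_cap see [tremor_config()].
#' @return list with `frequency` (Hz), `n_cycles`, `events` (crossing
#'   times, s), `hysteresis`, `no_tremor`.
#' @export
estimate_frequency <- function(signal, time = NULL, amplitude_floor = 0.5,
                               hysteresis = NULL, hysteresis_mult = 3,
                               hysteresis_cap = 0.25) {
  s <- as.numeric(signal)
  tt <- time %||% attr(signal, "time")
  check_that(!is.null(tt) && length(tt) == length(s),
             "need sample times matching the signal")
  check_that(max(tt) - min(tt) >= 1, "window must span at least 1 s")
  hb <- hysteresis_band(s, amplitude_floor, hysteresis_mult, hysteresis_cap)
  h <- hysteresis %||% hb$h
  if (hb$a_rob < amplitude_floor) {
    return(list(frequency = 0, n_cycles = 0L, events = numeric(0),
                hysteresis = h, no_tremor = TRUE))
  }
  ev <- schmitt_crossings(s, tt, h)
  if (length(ev) < 2L) {
    return(list(frequency = 0, n_cycles = 0L, events = ev, hysteresis = h,
                no_tremor = TRUE))
  }
  n_cyc <- length(ev) - 1L
  list(frequency = n_cyc / (ev[length(ev)] - ev[1L]),
       n_cycles = n_cyc, events = ev, hysteresis = h, no_tremor = FALSE)
}

# Per-cycle amplitudes. Cycles are delimited by consecutive positive-going
# crossing events. method "sine_fit": least-squares fit of
# c0 + c1*t + a*sin(2*pi*f_k*t) + b*cos(2*pi*f_k*t) at the cycle's own
# frequency, over the cycle's samples (symmetrically extended until at least
# `min_points` samples are available); amplitude = 2*sqrt(a^2+b^2). The
# trend term absorbs local drift, so the fit can run on the raw projection.
# method "sample_ptp": max - min of the samples inside the cycle.
cycle_amplitudes <- function(s, tt, events,
                             method = c("sine_fit", "sample_ptp"),
                             min_points = 8L) {
  method <- match.arg(method)
  nc <- length(events) - 1L
  amps <- numeric(nc)
  durations <- diff(events)
  # single crossing intervals are noisy at coarse sampling; a 5-cycle
  # running mean gives a stable local frequency for the per-cycle fit
  smooth_freq <- vapply(seq_len(nc), function(k) {
    j <- max(1L, k - 2L):min(nc, k + 2L)
    1 / mean(durations[j])
  }, numeric(1))
  for (k in seq_len(nc)) {
    t0 <- events[k]; t1 <- events[k + 1L]
    inside <- which(tt >= t0 & tt < t1)
    if (method == "sample_ptp") {
      amps[k] <- if (length(inside) >= 2L)
        max(s[inside]) - min(s[inside]) else NA_real_
      next
    }
    fk <- smooth_freq[k]
    idx <- inside
    ext <- 0L
    while (length(idx) < min_points &&
           (min(idx) > 1L || max(idx) < length(s))) {
      ext <- ext + 1L
      idx <- max(1L, min(inside) - ext):min(length(s), max(inside) + ext)
    }
    tc <- tt[idx] - t0
    y <- s[idx]
    fit_at <- function(f) {
      Xd <- cbind(1, tc, sin(2 * pi * f * tc), cos(2 * pi * f * tc))
      cf <- tryCatch(qr.coef(qr(Xd), y), error = function(e) rep(NA_real_, 4))
      cf[is.na(cf)] <- 0
      list(cf = cf, rss = sum((y - Xd %*% cf)^2))
    }
    # crossing-time interpolation is coarse near Nyquist; refine the local
    # frequency by least squares, but only within a narrow band so noise
    # cannot drive the fit into a degenerate (collinear) regime
    fk <- tryCatch(
      stats::optimize(function(f) fit_at(f)$rss,
                      interval = c(0.94, 1.06) * fk, tol = fk * 1e-5)$minimum,
      error = function(e) fk)
    cf <- fit_at(fk)$cf
    amps[k] <- 2 * sqrt(cf[3L]^2 + cf[4L]^2)
  }
  amps[is.finite(amps)]
}

#' Geometric-mean cycle amplitude
#'
#' The tremor amplitude of a window is the geometric mean of per-cycle
#' peak-to-peak amplitudes, cycles being delimited by the positive-going
#' zero crossings of the detrended tremor signal. Cycles whose amplitude
#' falls below the noise floor are excluded (and counted). By default each
#' cycle's amplitude comes from a local sinusoid least-squares fit, which
#' remains accurate when 25 fps sampling leaves only a few samples per
#' cycle; `method = "sample_ptp"` gives the naive sample excursion instead.
#'
#' @param signal a [tremor_signal()] (its raw, baseline-kept projection is
#'   used for fitting when available) or plain numeric vector.
#' @param time sample times, s.
#' @param events crossing times from [estimate_frequency()]; computed
#'   internally when omitted.
#' @param noise_floor minimum admissible cycle amplitude, mm; defaults to
#'   twice the hysteresis band.
#' @param method `"sine_fit"` or `"sample_ptp"`.
#' @param amplitude_floor passed to [estimate_frequency()] when `events` is
#'   omitted.
#' @return list with `amplitude` (mm, geometric mean), `per_cycle`,
#'   `n_cycles`, `n_excluded`.
#' @export
amplitude_geometric_mean <- function(signal, time = NULL, events = NULL,
                                     noise_floor = NULL,
                                     method = c("sine_fit", "sample_ptp"),
                                     amplitude_floor = 0.5) {
  method <- match.arg(method)
  s_det <- as.numeric(signal)
  tt <- time %||% attr(signal, "time")
  check_that(!is.null(tt) && length(tt) == length(s_det),
             "need sample times matching the signal")
  h <- NULL
  if (is.null(events)) {
    fe <- estimate_frequency(signal, tt, amplitude_floor = amplitude_floor)
    events <- fe$events
    h <- fe$hysteresis
  }
  check_that(length(events) >= 2L,
             "amplitude undefined: no complete tremor cycle in the window")
  if (is.null(noise_floor)) {
    if (is.null(h)) {
      h <- hysteresis_band(s_det, amplitude_floor)$h
    }
    noise_floor <- 2 * h
  }
  s_fit <- attr(signal, "raw") %||% s_det
  amps <- cycle_amplitudes(s_fit, tt, events, method = method)
  keep <- amps >= noise_floor
  check_that(any(keep), "amplitude undefined: all cycles below noise floor")
  list(amplitude = geomean(amps[keep]), per_cycle = amps,
       n_cycles = length(amps), n_excluded = sum(!keep))
}

# Detect the drawing span: first and last runs where speed exceeds
# `speed_threshold` mm/s for at least `speed_sustain` s. Returns sample
# index range (on the trajectory).
detect_drawing_span <- function(kin, fps, speed_threshold = 5,
                                speed_sustain = 0.2) {
  fast <- kin$velocity > speed_threshold
  need <- max(1L, as.integer(round(speed_sustain * fps)))
  r <- rle(fast)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= need)
  check_that(length(ok) > 0,
             "empty drawing span: no sustained motion above %.3g mm/s",
             speed_threshold)
  c(starts[ok[1L]], ends[ok[length(ok)]] + 1L)  # +1: displacement i spans i..i+1
}

#' Cumulative path length
#'
#' Total length of movement of the tracked point over the drawing span: the
#' sum of frame-to-frame displacements. The span is detected as the first
#' to last sustained motion above a speed threshold, or supplied explicitly.
#'
#' @param traj a calibrated [trajectory_series()].
#' @param span optional `c(first, last)` sample indices of the drawing span.
#' @param speed_threshold,speed_sustain span detection parameters (mm/s, s).
#' @return the cumulative length in mm, with the span indices attached as
#'   attribute `"span"`.
#' @export
cumulative_length <- function(traj, span = NULL, speed_threshold = 5,
                              speed_sustain = 0.2) {
  traj <- as_mm(traj)
  kin <- compute_kinematics(traj)
  if (is.null(span)) {
    span <- detect_drawing_span(kin, traj_fps(traj), speed_threshold,
                                speed_sustain)
  }
  check_that(length(span) == 2L && span[2L] > span[1L] &&
               span[1L] >= 1 && span[2L] <= nrow(traj),
             "empty or invalid drawing span")
  len <- sum(kin$displacement[span[1L]:(span[2L] - 1L)])
  attr(len, "span") <- span
  len
}

#' Summarise one task recording as tremor metrics
#'
#' Computes the five videographic tremor parameters for one task instance.
#' For the postural task the 10 s highest-amplitude window is selected
#' first and all parameters are computed on it; for the drawing task the
#' parameters (including cumulative length) are computed over the detected
#' drawing span, with the tremor signal taken as the deviation perpendicular
#' to the best-fit drawn line. The acceleration summary is the mean of
#' absolute frame accelerations (signed accelerations average to ~0 over an
#' oscillation).
#'
#' @param traj a calibrated [trajectory_series()].
#' @param task `"postural"` or `"drawing"`.
#' @param config a [tremor_config()].
#' @param span optional explicit drawing span (sample indices).
#' @return an object of class `tremor_metrics`: `mean_velocity` (mm/s),
#'   `mean_acceleration` (mm/s^2), `mean_frequency` (Hz), `amplitude` (mm,
#'   geometric mean; `NA` with `no_tremor = TRUE` when no cycle clears the
#'   noise floor), `cumulative_length` (mm, drawing only), `n_cycles`,
#'   `window`.
#' @export
summarize_task <- function(traj, task = c("postural", "drawing"),
                           config = tremor_config(), span = NULL) {
  task <- match.arg(task)
  stopifnot(inherits(config, "tremor_config"))
  traj <- as_mm(traj)

  if (task == "postural") {
    win <- select_analysis_window(traj, config$window_length,
                                  config$search_start, config$search_end,
                                  config$envelope_window,
                                  config$detrend_window)
    wtraj <- traj_subset(traj, win$idx)
    sig <- tremor_signal(wtraj, config$detrend_window)
    cum_len <- NA_real_
  } else {
    kin0 <- compute_kinematics(traj)
    if (is.null(span)) {
      span <- detect_drawing_span(kin0, traj_fps(traj),
                                  config$speed_threshold,
                                  config$speed_sustain)
    }
    win <- structure(list(start = traj$time[span[1L]],
                          end = traj$time[span[2L]],
                          center = mean(traj$time[span]),
                          window_length = diff(traj$time[span]),
                          idx = span[1L]:span[2L]),
                     class = "analysis_window")
    wtraj <- traj_subset(traj, win$idx)
    sig <- drawing_deviation_signal(wtraj, config$detrend_window)
    cum_len <- as.numeric(cumulative_length(traj, span = span))
  }

  kin <- compute_kinematics(wtraj)
  fe <- estimate_frequency(sig, amplitude_floor = config$amplitude_floor,
                           hysteresis_mult = config$hysteresis_mult,
                           hysteresis_cap = config$hysteresis_cap)
  if (!fe$no_tremor && fe$n_cycles >= 1L) {
    am <- amplitude_geometric_mean(sig, events = fe$events,
                                   noise_floor = 2 * fe$hysteresis,
                                   method = config$amplitude_method)
    amplitude <- am$amplitude
    n_cycles <- am$n_cycles
  } else {
    amplitude <- NA_real_
    n_cycles <- 0L
  }

  structure(list(task = task,
                 mean_velocity = mean(kin$velocity),
                 mean_acceleration = mean(abs(kin$acceleration)),
                 mean_frequency = fe$frequency,
                 amplitude = amplitude,
                 cumulative_length = cum_len,
                 n_cycles = n_cycles,
                 no_tremor = fe$no_tremor,
                 window = win),
            class = "tremor_metrics")
}

# Tremor signal of the drawing task: deviation perpendicular to the best-fit
# line through the span (first principal direction of the positions), with
# the detrended component used for cycle delimitation and the raw deviation
# kept for amplitude fitting.
drawing_deviation_signal <- function(traj, detrend_window = 1) {
  X <- cbind(traj$x, traj$y)
  Xc <- sweep(X, 2L, colMeans(X))
  e <- eigen(crossprod(Xc) / nrow(Xc), symmetric = TRUE)
  perp <- e$vectors[, 2L]                 # minor axis = perpendicular
  if ((if (abs(perp[1L]) >= abs(perp[2L])) perp[1L] else perp[2L]) < 0) {
    perp <- -perp
  }
  raw <- as.numeric(Xc %*% perp)
  tt <- traj$time
  det <- raw - local_linear_baseline(raw, tt, detrend_window)
  det <- det - mean(det)
  structure(det, time = tt, fps = traj_fps(traj), axis = perp,
            raw = raw - mean(raw), class = "tremor_signal")
}

#' @export
print.tremor_metrics <- function(x, ...) {
  cat(sprintf("<tremor_metrics> %s task%s\n", x$task,
              if (x$no_tremor) " [no tremor detected]" else ""))
  cat(sprintf("  velocity     %8.2f mm/s\n", x$mean_velocity))
  cat(sprintf("  acceleration %8.2f mm/s^2\n", x$mean_acceleration))
  cat(sprintf("  frequency    %8.2f Hz (%d cycles)\n", x$mean_frequency,
              x$n_cycles))
  cat(sprintf("  amplitude    %8.2f mm\n", x$amplitude))
  if (!is.na(x$cumulative_length)) {
    cat(sprintf("  cum. length  %8.2f mm\n", x$cumulative_length))
  }
  invisible(x)
}

#' Log10 treatment change of a videographic parameter
#'
#' The pre/post treatment change measure: `log10(T2 / T1)`, negative when
#' tremor improves.
#'
#' @param t1 pre-treatment value (> 0).
#' @param t2 post-treatment value (> 0).
#' @return `log10(t2) - log10(t1)` (vectorised).
#' @examples
#' log_change(14.0, 2.7)   # ~ -0.715
#' @export
log_change <- function(t1, t2) {
  check_that(is.numeric(t1) && is.numeric(t2) &&
               all(is.finite(t1)) && all(is.finite(t2)) &&
               all(t1 > 0) && all(t2 > 0),
             "log_change requires strictly positive finite values")
  log10(t2) - log10(t1)
}
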