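#' Specify a synthetic tremor signal
#'
#' Describes a quasi-sinusoidal tremor: a carrier oscillation of given
#' frequency and peak-to-peak amplitude along a dominant axis in the image
#' plane, with optional per-cycle frequency jitter, sinusoidal amplitude
#' modulation, slow linear baseline drift, and additive isotropic Gaussian
#' observation noise. Defaults emulate a moderate essential tremor as seen
#' in wing-beat recordings: 5 Hz, 20 mm peak-to-peak (a CRST Part A rating
#' of about 2), filmed for 60 s at 25 frames per second.
#'
#' @param base_frequency carrier frequency in Hz (> 0).
#' @param peak_to_peak_amplitude carrier peak-to-peak amplitude in mm (>= 0).
#' @param frequency_jitter_sd SD of per-cycle frequency deviations, Hz.
#' @param amplitude_mod_depth fractional depth of sinusoidal amplitude
#'   modulation, in `[0, 1)`.
#' @param amplitude_mod_frequency modulation frequency in Hz.
#' @param drift_velocity slow baseline wander, mm/s (applied along the image
#'   x axis).
#' @param noise_sd SD of additive observation noise per axis, mm.
#' @param tremor_axis_angle orientation of the dominant oscillation axis in
#'   the image plane, degrees (0 = horizontal).
#' @param duration recording length, s.
#' @param fps frame rate, frames/s.
#' @param seed integer RNG seed; identical spec + seed reproduce the signal
#'   bit for bit.
#' @return an object of class `tremor_spec`.
#' @export
tremor_spec <- function(base_frequency = 5, peak_to_peak_amplitude = 20,
                        frequency_jitter_sd = 0, amplitude_mod_depth = 0,
                        amplitude_mod_frequency = 0.5, drift_velocity = 0,
                        noise_sd = 0, tremor_axis_angle = 0,
                        duration = 60, fps = 25, seed = 1L) {
  check_scalar(base_frequency, "base_frequency", min = 0, strict_min = TRUE)
  check_scalar(peak_to_peak_amplitude, "peak_to_peak_amplitude", min = 0)
  check_scalar(frequency_jitter_sd, "frequency_jitter_sd", min = 0)
  check_scalar(amplitude_mod_depth, "amplitude_mod_depth", min = 0, max = 1,
               strict_max = TRUE)
  check_scalar(amplitude_mod_frequency, "amplitude_mod_frequency", min = 0)
  check_scalar(drift_velocity, "drift_velocity")
  check_scalar(noise_sd, "noise_sd", min = 0)
  check_scalar(tremor_axis_angle, "tremor_axis_angle")
  check_scalar(duration, "duration", min = 0, strict_min = TRUE)
  check_scalar(fps, "fps", min = 0, strict_min = TRUE)
  structure(list(base_frequency = base_frequency,
                 peak_to_peak_amplitude = peak_to_peak_amplitude,
                 frequency_jitter_sd = frequency_jitter_sd,
                 amplitude_mod_depth = amplitude_mod_depth,
                 amplitude_mod_frequency = amplitude_mod_frequency,
                 drift_velocity = drift_velocity,
                 noise_sd = noise_sd,
                 tremor_axis_angle = tremor_axis_angle,
                 duration = duration, fps = fps, seed = seed),
            class = "tremor_spec")
}

#' @export
print.tremor_spec <- function(x, ...) {
  cat(sprintf(paste0("<tremor_spec> %g Hz, %g mm pk-pk, jitter %g Hz, ",
                     "mod %g @ %g Hz,\n  drift %g mm/s, noise %g mm, ",
                     "axis %g deg, %g s @ %g fps, seed %s\n"),
              x$base_frequency, x$peak_to_peak_amplitude,
              x$frequency_jitter_sd, x$amplitude_mod_depth,
              x$amplitude_mod_frequency, x$drift_velocity, x$noise_sd,
              x$tremor_axis_angle, x$duration, x$fps, x$seed))
  invisible(x)
}

# Piecewise-linear phase function with per-cycle frequency jitter. Returns a
# closure phase(t) in radians; cycle k has constant frequency f_k drawn as
# base + N(0, jitter_sd), truncated below at base/10 to stay positive.
make_phase_fun <- function(base, jitter_sd, duration) {
  if (jitter_sd <= 0) {
    force(base)
    return(function(tt) 2 * pi * base * tt)
  }
  n_max <- ceiling(duration * (base + 6 * jitter_sd)) + 2L
  fk <- base + rnorm(n_max, 0, jitter_sd)
  fk <- pmax(fk, base / 10)
  bounds <- c(0, cumsum(1 / fk))           # cycle boundary times
  while (bounds[length(bounds)] <= duration) {
    f_extra <- pmax(base + rnorm(n_max, 0, jitter_sd), base / 10)
    fk <- c(fk, f_extra)
    bounds <- c(0, cumsum(1 / fk))
  }
  function(tt) {
    k <- findInterval(tt, bounds, rightmost.closed = FALSE)
    k <- pmin(k, length(fk))
    2 * pi * ((k - 1) + (tt - bounds[k]) * fk[k])
  }
}

# Noise-free closed-form position (mm) shared by both generators; returned as
# the "truth" attribute so tests can integrate arc length or compare envelopes.
make_truth_fun <- function(spec, phase_fun, envelope_fun = NULL,
                           line_fun = NULL) {
  theta <- spec$tremor_axis_angle * pi / 180
  ux <- cos(theta); uy <- sin(theta)
  amp <- spec$peak_to_peak_amplitude / 2
  m <- spec$amplitude_mod_depth
  fm <- spec$amplitude_mod_frequency
  drift <- spec$drift_velocity
  function(tt) {
    a <- amp * (1 + m * sin(2 * pi * fm * tt))
    s <- a * sin(phase_fun(tt))
    if (!is.null(envelope_fun)) s <- s * envelope_fun(tt)
    if (is.null(line_fun)) {
      cbind(x = s * ux + drift * tt, y = s * uy)
    } else {
      # drawing task: tremor perpendicular to the drawn line
      cbind(x = line_fun(tt), y = s + drift * tt)
    }
  }
}

#' Generate a synthetic postural (wing-beat) tremor trajectory
#'
#' Simulates the fingertip path recorded during a 60 s postural hold: the
#' tremor oscillation of [tremor_spec()] along its axis, superimposed on
#' linear drift, plus isotropic Gaussian observation noise. The noise-free
#' generating curve is attached as attribute `"truth"` (a function of time).
#'
#' @param spec a [tremor_spec()].
#' @return a [trajectory_series()] in mm with `duration * fps + 1` samples.
#' @export
generate_postural_trajectory <- function(spec) {
  stopifnot(inherits(spec, "tremor_spec"))
  with_seed(spec$seed, {
    n <- as.integer(round(spec$duration * spec$fps)) + 1L
    tt <- (seq_len(n) - 1L) / spec$fps
    phase_fun <- make_phase_fun(spec$base_frequency, spec$frequency_jitter_sd,
                                spec$duration)
    truth <- make_truth_fun(spec, phase_fun)
    pos <- truth(tt)
    if (spec$noise_sd > 0) {
      pos[, 1L] <- pos[, 1L] + rnorm(n, 0, spec$noise_sd)
      pos[, 2L] <- pos[, 2L] + rnorm(n, 0, spec$noise_sd)
    }
    out <- trajectory_series(pos[, 1L], pos[, 2L], spec$fps, units = "mm")
    attr(out, "truth") <- truth
    attr(out, "spec") <- spec
    out
  })
}

#' Generate a synthetic 15 cm line-drawing trajectory
#'
#' Simulates the pen tip connecting two dots: a constant-velocity traversal
#' of a horizontal segment with the tremor oscillation of the spec
#' superimposed perpendicular to the line. The tremor is tapered to zero
#' over a short ramp at both ends (the pen is anchored on the dots), so the
#' endpoints' net displacement equals `line_length` whenever noise and drift
#' are absent.
#'
#' @param spec a [tremor_spec()]; `duration` and `tremor_axis_angle` are
#'   ignored (the line fixes both timing and geometry).
#' @param line_length length of the drawn segment, mm.
#' @param draw_duration time taken to draw the line, s.
#' @param taper ramp time over which tremor fades in/out at the endpoints, s.
#' @return a [trajectory_series()] in mm with `draw_duration * fps + 1`
#'   samples; noise-free generating curve in attribute `"truth"`.
#' @export
generate_drawing_trajectory <- function(spec, line_length = 150,
                                        draw_duration = 5, taper = 0.3) {
  stopifnot(inherits(spec, "tremor_spec"))
  check_scalar(line_length, "line_length", min = 0, strict_min = TRUE)
  check_scalar(draw_duration, "draw_duration", min = 0, strict_min = TRUE)
  check_scalar(taper, "taper", min = 0, max = draw_duration / 2)
  with_seed(spec$seed, {
    n <- as.integer(round(draw_duration * spec$fps)) + 1L
    tt <- (seq_len(n) - 1L) / spec$fps
    phase_fun <- make_phase_fun(spec$base_frequency, spec$frequency_jitter_sd,
                                draw_duration)
    envelope_fun <- if (taper > 0) {
      function(x) pmin(1, x / taper, (draw_duration - x) / taper)
    } else NULL
    line_fun <- function(x) line_length * x / draw_duration
    truth <- make_truth_fun(spec, phase_fun, envelope_fun, line_fun)
    pos <- truth(tt)
    if (spec$noise_sd > 0) {
      pos[, 1L] <- pos[, 1L] + rnorm(n, 0, spec$noise_sd)
      pos[, 2L] <- pos[, 2L] + rnorm(n, 0, spec$noise_sd)
    }
    out <- trajectory_series(pos[, 1L], pos[, 2L], spec$fps, units = "mm")
    attr(out, "truth") <- truth
    attr(out, "spec") <- spec
    out
  })
}
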