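test_that("displacement, velocity and acceleration follow the frame formulas", {
  # 3-4-5 step at 25 fps: displacement 5 mm, velocity 125 mm/s
  k <- compute_kinematics(make_traj(c(0, 3, 3), c(0, 4, 4)))
  expect_identical(k$displacement[1], 5)
  expect_identical(k$velocity[1], 125)
  # velocities 100 then 125 mm/s: acceleration (125-100)/0.04 = 625 mm/s^2
  k2 <- compute_kinematics(make_traj(c(0, 4, 9), c(0, 0, 0)))
  expect_identical(k2$velocity, c(100, 125))
  expect_identical(k2$acceleration, 625)
  # constant position: all zero
  k0 <- compute_kinematics(make_traj(rep(1, 10), rep(2, 10)))
  expect_true(all(k0$displacement == 0) && all(k0$velocity == 0) &&
                all(k0$acceleration == 0))
  # uncalibrated pixel trajectory cannot produce mm kinematics
  px <- trajectory_series(c(0, 1, 2), c(0, 0, 0), 25, units = "px")
  expect_error(compute_kinematics(px), "uncalibrated")
})

test_that("tremor signal projects onto the oscillation axis and removes drift", {
  tt <- seq(0, 10, by = 1 / 100)
  # planar sinusoid along a 30 degree axis, half-amplitude 7 mm
  s <- 7 * sin(2 * pi * 4 * tt)
  tr <- make_traj(s * cos(pi / 6), s * sin(pi / 6), fps = 100)
  sig <- tremor_signal(tr)
  expect_equal(diff(range(sig)), 14, tolerance = 0.02 * 14)
  ax <- attr(sig, "axis")
  expect_equal(abs(sum(ax * c(cos(pi / 6), sin(pi / 6)))), 1,
               tolerance = 1e-6)
  # pure linear drift leaves ~zero residual
  trd <- make_traj(3 * tt, -1.5 * tt, fps = 100)
  sigd <- tremor_signal(trd)
  expect_lt(sqrt(mean(sigd^2)), 1e-8)
  # sinusoid + drift: detrended signal matches the sinusoid closely
  trsd <- make_traj(7 * sin(2 * pi * 5 * tt) + 2 * tt, rep(0, length(tt)),
                    fps = 100)
  sigsd <- tremor_signal(trsd)
  ref <- 7 * sin(2 * pi * 5 * tt)
  interior <- tt >= 0.5 & tt <= max(tt) - 0.5   # past the filter edge ramp
  expect_lt(sqrt(mean((as.numeric(sigsd)[interior] - ref[interior])^2)) / 7,
            0.03)
  # constant trajectory: zero signal, not an error
  sig0 <- tremor_signal(make_traj(rep(1, 300), rep(1, 300), fps = 100))
  expect_true(all(sig0 == 0))
})

test_that("the highest-amplitude window rule centres, clamps and tie-breaks", {
  fps <- 25
  tt <- seq(0, 60, by = 1 / fps)
  burst_traj <- function(t_burst) {
    amp <- 2 + 8 * exp(-((tt - t_burst) / 1.5)^2)
    make_traj(amp * sin(2 * pi * 5 * tt), rep(0, length(tt)), fps)
  }
  w30 <- select_analysis_window(burst_traj(30))
  expect_equal(w30$center, 30, tolerance = 0.3)
  expect_equal(w30$end - w30$start, 10)
  expect_length(w30$idx, 10 * fps + 1)

  # burst before the admissible range: centre clamps to 5 -> window [0, 10]
  w3 <- select_analysis_window(burst_traj(3))
  expect_equal(w3$center, 5)
  expect_equal(c(w3$start, w3$end), c(0, 10))

  # constant amplitude everywhere: tie broken at the earliest centre
  flat <- make_traj(5 * sin(2 * pi * 5 * tt), rep(0, length(tt)), fps)
  wf <- select_analysis_window(flat)
  expect_equal(wf$center, 5)

  # too-short recording errors with the minimum duration
  short <- make_traj(sin(2 * pi * 5 * tt[tt <= 30]), rep(0, sum(tt <= 30)),
                     fps)
  expect_error(select_analysis_window(short), "60.0 s")
})

test_that("frequency counts average waves per second", {
  tt <- seq(0, 10, by = 1 / 25)
  f4 <- estimate_frequency(structure(10 * sin(2 * pi * 4 * tt), time = tt))
  expect_equal(f4$frequency, 4, tolerance = 1e-3)
  fslow <- estimate_frequency(structure(10 * sin(2 * pi * 0.5 * tt),
                                        time = tt))
  expect_equal(fslow$frequency, 0.5, tolerance = 1e-3)
  # linear chirp 3 -> 5 Hz: phase = 2*pi*(3t + t^2/10), mean frequency 4
  chirp <- 10 * sin(2 * pi * (3 * tt + tt^2 / 10))
  fc <- estimate_frequency(structure(chirp, time = tt))
  expect_equal(fc$frequency, 4, tolerance = 0.1)
  # zero signal: 0 Hz with the no-tremor flag
  f0 <- estimate_frequency(structure(rep(0, length(tt)), time = tt))
  expect_identical(f0$frequency, 0)
  expect_true(f0$no_tremor)
})

test_that("geometric-mean amplitude matches per-cycle constructions", {
  tt <- seq(0, 10, by = 1 / 100)
  # constant 20 mm peak-to-peak sinusoid
  sig <- structure(10 * sin(2 * pi * 4 * tt), time = tt)
  am <- amplitude_geometric_mean(sig)
  expect_equal(am$amplitude, 20, tolerance = 0.01)
  # alternating cycle amplitudes 10 and 40 mm -> geometric mean 20
  period <- 0.25
  cyc <- floor(tt / period)
  alt <- ifelse(cyc %% 2 == 0, 5, 20) * sin(2 * pi * 4 * tt)
  am2 <- amplitude_geometric_mean(structure(alt, time = tt))
  expect_equal(am2$amplitude, 20, tolerance = 0.02 * 20)
  # amplitude-modulated signal vs brute-force per-cycle oracle
  a_t <- 10 * (1 + 0.3 * sin(2 * pi * 0.4 * tt))
  mod <- a_t * sin(2 * pi * 4 * tt)
  amm <- amplitude_geometric_mean(structure(mod, time = tt))
  fe <- estimate_frequency(structure(mod, time = tt))
  dense_t <- seq(0, 10, by = 1e-4)
  dense <- 10 * (1 + 0.3 * sin(2 * pi * 0.4 * dense_t)) *
    sin(2 * pi * 4 * dense_t)
  per_cycle <- vapply(seq_len(length(fe$events) - 1), function(k) {
    j <- dense_t >= fe$events[k] & dense_t < fe$events[k + 1]
    max(dense[j]) - min(dense[j])
  }, numeric(1))
  expect_equal(amm$amplitude, exp(mean(log(per_cycle))), tolerance = 0.03)
  # no complete cycles: undefined amplitude
  expect_error(
    amplitude_geometric_mean(structure(rep(0, 201), time = seq(0, 2, 0.01))),
    "no complete")
})

test_that("cumulative length obeys path geometry", {
  # closed square of side 10 mm
  sq <- make_traj(c(0, 10, 10, 0, 0), c(0, 0, 10, 10, 0))
  k <- compute_kinematics(sq)
  expect_identical(sum(k$displacement), 40)
  expect_identical(as.numeric(cumulative_length(sq, span = c(1, 5))), 40)
  # straight constant-speed 150 mm line, detected span
  d0 <- generate_drawing_trajectory(
    tremor_spec(peak_to_peak_amplitude = 0, noise_sd = 0), 150, 5)
  expect_equal(as.numeric(cumulative_length(d0)), 150, tolerance = 1e-9)
  # tremulous line: longer than the chord and matches arc-length quadrature
  dt <- generate_drawing_trajectory(
    tremor_spec(base_frequency = 4, peak_to_peak_amplitude = 20, fps = 200,
                seed = 2), 150, 5)
  cl <- as.numeric(cumulative_length(dt))
  expect_gt(cl, 150)
  expect_equal(cl, oracle_arc_length(attr(dt, "truth"), 0, 5),
               tolerance = 0.02)
  # no motion at all: empty span
  still <- make_traj(rep(0, 100), rep(0, 100))
  expect_error(cumulative_length(still), "empty")
})

test_that("task summaries recover generator ground truth", {
  sp <- tremor_spec(base_frequency = 5, peak_to_peak_amplitude = 30,
                    noise_sd = 0.3, duration = 60, fps = 25, seed = 17)
  m <- summarize_task(generate_postural_trajectory(sp), "postural")
  expect_equal(m$mean_frequency, 5, tolerance = 0.1)
  expect_equal(m$amplitude, 30, tolerance = 1.5)
  expect_gt(m$mean_velocity, 0)
  expect_gt(m$mean_acceleration, 0)
  # zero-amplitude trajectory: no-tremor flag, undefined amplitude
  m0 <- summarize_task(generate_postural_trajectory(
    tremor_spec(peak_to_peak_amplitude = 0, noise_sd = 0.05, duration = 60)),
    "postural")
  expect_true(m0$no_tremor)
  expect_true(is.na(m0$amplitude))
  # drawing with no tremor: cumulative length equals the line
  md <- summarize_task(generate_drawing_trajectory(
    tremor_spec(peak_to_peak_amplitude = 0, noise_sd = 0), 150, 5),
    "drawing")
  expect_equal(md$cumulative_length, 150, tolerance = 1e-9)
})

test_that("metrics are invariant under rigid motions and scale linearly", {
  sp <- tremor_spec(base_frequency = 4.5, peak_to_peak_amplitude = 25,
                    noise_sd = 0.2, duration = 60, fps = 25, seed = 23)
  tr <- generate_postural_trajectory(sp)
  m <- summarize_task(tr, "postural")
  # translation + rotation
  th <- 0.7
  xr <- cos(th) * tr$x - sin(th) * tr$y + 40
  yr <- sin(th) * tr$x + cos(th) * tr$y - 15
  mr <- summarize_task(make_traj(xr, yr), "postural")
  expect_equal(mr$amplitude, m$amplitude, tolerance = 1e-6 * m$amplitude)
  expect_equal(mr$mean_frequency, m$mean_frequency, tolerance = 1e-6)
  expect_equal(mr$mean_velocity, m$mean_velocity,
               tolerance = 1e-6 * m$mean_velocity)
  # uniform scaling doubles amplitude and velocity, leaves frequency alone
  ms <- summarize_task(make_traj(2 * tr$x, 2 * tr$y), "postural")
  expect_equal(ms$amplitude, 2 * m$amplitude, tolerance = 0.01 * m$amplitude)
  expect_equal(ms$mean_velocity, 2 * m$mean_velocity,
               tolerance = 1e-6 * m$mean_velocity)
  expect_equal(ms$mean_frequency, m$mean_frequency, tolerance = 1e-3)
  # cumulative length >= endpoint distance, always
  dtr <- generate_drawing_trajectory(
    tremor_spec(base_frequency = 5, peak_to_peak_amplitude = 30,
                noise_sd = 0.5, seed = 31), 150, 5)
  cl <- as.numeric(cumulative_length(dtr, span = c(1, nrow(dtr))))
  chord <- sqrt(diff(dtr$x[c(1, nrow(dtr))])^2 +
                  diff(dtr$y[c(1, nrow(dtr))])^2)
  expect_gte(cl, chord)
})

test_that("log change is the antisymmetric log10 ratio", {
  expect_identical(log_change(10, 1), -1)
  expect_identical(log_change(7, 7), 0)
  expect_equal(log_change(14.0, 2.7), log10(2.7 / 14.0))
  expect_equal(log_change(14.0, 2.7), -0.7147, tolerance = 1e-4)
  for (pair in list(c(3, 17), c(0.2, 5), c(110, 4))) {
    expect_identical(log_change(pair[1], pair[2]),
                     -log_change(pair[2], pair[1]))
  }
  expect_error(log_change(0, 1), "positive")
  expect_error(log_change(5, -2), "positive")
})
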