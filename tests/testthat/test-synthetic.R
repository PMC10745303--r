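test_that("postural generator honours sample count, amplitude and determinism", {
  sp <- tremor_spec(base_frequency = 4, peak_to_peak_amplitude = 20,
                    duration = 60, fps = 25, seed = 1)
  tr <- generate_postural_trajectory(sp)
  expect_equal(nrow(tr), 1501L)
  # noiseless sinusoid along the x axis spans the requested peak-to-peak
  expect_equal(diff(range(tr$x)), 20, tolerance = 5e-3)
  expect_equal(diff(range(tr$y)), 0)

  # axis rotation moves the oscillation onto the requested direction
  sp30 <- tremor_spec(base_frequency = 4, peak_to_peak_amplitude = 20,
                      tremor_axis_angle = 30, duration = 10, seed = 1)
  tr30 <- generate_postural_trajectory(sp30)
  proj <- tr30$x * cos(pi / 6) + tr30$y * sin(pi / 6)
  expect_equal(diff(range(proj)), 20, tolerance = 5e-3)

  # zero amplitude, zero noise: constant trajectory
  tr0 <- generate_postural_trajectory(
    tremor_spec(peak_to_peak_amplitude = 0, noise_sd = 0, duration = 5))
  expect_equal(diff(range(tr0$x)), 0)
  expect_equal(diff(range(tr0$y)), 0)

  # determinism contract: same spec + seed => identical arrays
  spn <- tremor_spec(noise_sd = 1, frequency_jitter_sd = 0.3, duration = 10,
                     seed = 99)
  a <- generate_postural_trajectory(spn)
  b <- generate_postural_trajectory(spn)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  c_ <- generate_postural_trajectory(
    tremor_spec(noise_sd = 1, frequency_jitter_sd = 0.3, duration = 10,
                seed = 100))
  expect_false(identical(a$x, c_$x))
})

test_that("tremor_spec validation names the offending field", {
  expect_error(tremor_spec(base_frequency = 0), "base_frequency")
  expect_error(tremor_spec(amplitude_mod_depth = 1), "amplitude_mod_depth")
  expect_error(tremor_spec(fps = -1), "fps")
  expect_error(tremor_spec(noise_sd = -0.1), "noise_sd")
})

test_that("drawing generator traverses the line and matches arc-length oracle", {
  # amplitude 0, noise 0: a straight 150 mm line, cumulative length exact
  sp0 <- tremor_spec(peak_to_peak_amplitude = 0, noise_sd = 0)
  d0 <- generate_drawing_trajectory(sp0, line_length = 150, draw_duration = 5)
  expect_equal(nrow(d0), 126L)
  expect_equal(sum(sqrt(diff(d0$x)^2 + diff(d0$y)^2)), 150)
  expect_equal(sqrt(diff(range(d0$x))^2), 150)

  # tremor makes the path strictly longer than the chord
  spt <- tremor_spec(base_frequency = 4, peak_to_peak_amplitude = 20,
                     fps = 200, seed = 2)
  dt <- generate_drawing_trajectory(spt, 150, 5)
  polyline <- sum(sqrt(diff(dt$x)^2 + diff(dt$y)^2))
  expect_gt(polyline, 150)

  # and matches quadrature of the generating closed-form curve
  arc <- oracle_arc_length(attr(dt, "truth"), 0, 5)
  expect_equal(polyline, arc, tolerance = 0.02)

  # endpoints' net displacement equals the line when noise-free
  spj <- tremor_spec(base_frequency = 5, peak_to_peak_amplitude = 15,
                     frequency_jitter_sd = 0.4, fps = 100, seed = 3)
  dj <- generate_drawing_trajectory(spj, 150, 5)
  net <- sqrt((dj$x[nrow(dj)] - dj$x[1])^2 + (dj$y[nrow(dj)] - dj$y[1])^2)
  expect_equal(net, 150, tolerance = 1e-9)
})

test_that("cohort generator reproduces its rating and treatment structure", {
  # noise-free ratings over a narrow amplitude band inside the scale:
  # rating is a monotone function of amplitude (rho = 1 up to rating ties)
  wf0 <- weber_fechner_spec(rating_noise_sd = 0, rating_min = -20,
                            rating_max = 20)
  co0 <- generate_cohort(cohort_spec(n_patients = 50, weber_fechner = wf0,
                                     seed = 5))
  ok <- !duplicated(co0$rating_pre)
  s <- spearman_rho(co0$rating_pre, log10(co0$amplitude_pre))
  expect_gt(s$rho, 0.99)

  # no treatment effect: paired log differences centred on zero
  con <- generate_cohort(cohort_spec(n_patients = 400,
                                     treatment_effect_log = 0,
                                     treatment_effect_log_sd = 0.1,
                                     seed = 6))
  expect_lt(abs(mean(log10(con$amplitude_post / con$amplitude_pre))), 0.02)

  # 0.7 log10 effect recovered from the generated cohort
  co7 <- generate_cohort(cohort_spec(n_patients = 200,
                                     treatment_effect_log = 0.7, seed = 7))
  mlc <- mean(log_change(co7$amplitude_pre, co7$amplitude_post))
  expect_equal(mlc, -0.7, tolerance = 0.05)

  # determinism
  expect_identical(generate_cohort(cohort_spec(seed = 11)),
                   generate_cohort(cohort_spec(seed = 11)))
})

test_that("rating-amplitude rank correlation degrades with rating noise", {
  mean_rho <- function(noise_sd) {
    rhos <- vapply(1:8, function(s) {
      wf <- weber_fechner_spec(rating_noise_sd = noise_sd)
      co <- generate_cohort(cohort_spec(n_patients = 150, weber_fechner = wf,
                                        seed = 100 + s))
      spearman_rho(co$rating_pre, log10(co$amplitude_pre))$rho
    }, numeric(1))
    mean(rhos)
  }
  r <- vapply(c(0.2, 1, 3), mean_rho, numeric(1))
  expect_true(all(diff(r) < 0))
})
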