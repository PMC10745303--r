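#' Specify a Weber-Fechner rating model
#'
#' Clinical tremor ratings behave as a quantized perception of log tremor
#' amplitude: on average, `log10(amplitude mm) = intercept_a + slope_b *
#' rating`. Ratings are generated by inverting this line, adding Gaussian
#' rating noise, rounding to the scale's grid and clipping to its range.
#' Defaults place rating 2 near 2 cm and rating 4 near 4 cm, matching the
#' amplitude anchors of CRST Part A (`intercept_a = 1`, `slope_b = 0.15`
#' give `10^(1 + 0.15*2) = 20` mm and `10^(1 + 0.15*4) = 40` mm).
#'
#' @param intercept_a log10-mm amplitude at rating 0.
#' @param slope_b log10-mm per rating point (> 0).
#' @param rating_noise_sd SD of perceptual/rater noise, rating points.
#' @param rating_min,rating_max scale range (integers, min < max).
#' @param rating_step grid of the scale: 1 for CRST-like integer scales,
#'   0.5 for TETRAS-like half-point scales.
#' @return an object of class `weber_fechner_spec`.
#' @export
weber_fechner_spec <- function(intercept_a = 1, slope_b = 0.15,
                               rating_noise_sd = 0.5,
                               rating_min = 0, rating_max = 4,
                               rating_step = 1) {
  check_scalar(intercept_a, "intercept_a")
  check_scalar(slope_b, "slope_b", min = 0, strict_min = TRUE)
  check_scalar(rating_noise_sd, "rating_noise_sd", min = 0)
  check_scalar(rating_min, "rating_min")
  check_scalar(rating_max, "rating_max")
  check_that(rating_min < rating_max, "invalid 'rating_min': must be < rating_max")
  check_scalar(rating_step, "rating_step", min = 0, strict_min = TRUE)
  structure(list(intercept_a = intercept_a, slope_b = slope_b,
                 rating_noise_sd = rating_noise_sd,
                 rating_min = rating_min, rating_max = rating_max,
                 rating_step = rating_step),
            class = "weber_fechner_spec")
}

# Draw ratings for amplitudes (mm) under a weber_fechner_spec. Uses the
# caller's RNG stream.
draw_ratings <- function(wf, amplitude_mm) {
  z <- (log10(amplitude_mm) - wf$intercept_a) / wf$slope_b
  if (wf$rating_noise_sd > 0) {
    z <- z + rnorm(length(z), 0, wf$rating_noise_sd)
  }
  r <- round(z / wf$rating_step) * wf$rating_step
  pmin(wf$rating_max, pmax(wf$rating_min, r))
}

#' Specify a synthetic patient cohort
#'
#' Per patient, a true pre-treatment tremor amplitude is drawn lognormally,
#' the post-treatment amplitude is the pre amplitude reduced by a treatment
#' effect on the log10 scale (with patient-level variability in response),
#' and clinical ratings are generated from amplitude through the noisy
#' Weber-Fechner relation. Defaults emulate a severe-ET surgical cohort:
#' 43 patients, median pre amplitude ~14 mm spanning roughly 2-90 mm, and a
#' 0.7 log10 (five-fold) amplitude reduction after treatment.
#'
#' @param n_patients cohort size (>= 2).
#' @param pre_amplitude_log_mean,pre_amplitude_log_sd mean and SD of
#'   pre-treatment log10 amplitude (log10-mm).
#' @param treatment_effect_log mean log10 amplitude reduction after
#'   treatment (positive = improvement).
#' @param treatment_effect_log_sd patient-level SD of the treatment effect
#'   (log10-mm).
#' @param weber_fechner a [weber_fechner_spec()] used to rate both visits.
#' @param seed integer RNG seed.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 43,
                        pre_amplitude_log_mean = log10(14),
                        pre_amplitude_log_sd = 0.4,
                        treatment_effect_log = 0.7,
                        treatment_effect_log_sd = 0.15,
                        weber_fechner = weber_fechner_spec(),
                        seed = 1L) {
  check_scalar(n_patients, "n_patients", min = 2)
  check_scalar(pre_amplitude_log_mean, "pre_amplitude_log_mean")
  check_scalar(pre_amplitude_log_sd, "pre_amplitude_log_sd", min = 0)
  check_scalar(treatment_effect_log, "treatment_effect_log")
  check_scalar(treatment_effect_log_sd, "treatment_effect_log_sd", min = 0)
  check_that(inherits(weber_fechner, "weber_fechner_spec"),
             "invalid 'weber_fechner': need a weber_fechner_spec")
  structure(list(n_patients = as.integer(n_patients),
                 pre_amplitude_log_mean = pre_amplitude_log_mean,
                 pre_amplitude_log_sd = pre_amplitude_log_sd,
                 treatment_effect_log = treatment_effect_log,
                 treatment_effect_log_sd = treatment_effect_log_sd,
                 weber_fechner = weber_fechner, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic rated cohort
#'
#' @param spec a [cohort_spec()].
#' @return a data frame of class `cohort_table` with one row per patient:
#'   `id`, true amplitudes `amplitude_pre` / `amplitude_post` (mm), their
#'   log10 values, and ratings `rating_pre` / `rating_post` drawn through
#'   the Weber-Fechner model.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_patients
    log_pre <- rnorm(n, spec$pre_amplitude_log_mean, spec$pre_amplitude_log_sd)
    effect <- spec$treatment_effect_log +
      rnorm(n, 0, spec$treatment_effect_log_sd)
    log_post <- log_pre - effect
    wf <- spec$weber_fechner
    out <- data.frame(id = sprintf("P%03d", seq_len(n)),
                      amplitude_pre = 10^log_pre,
                      amplitude_post = 10^log_post,
                      log_amplitude_pre = log_pre,
                      log_amplitude_post = log_post,
                      rating_pre = draw_ratings(wf, 10^log_pre),
                      rating_post = draw_ratings(wf, 10^log_post))
    attr(out, "spec") <- spec
    class(out) <- c("cohort_table", "data.frame")
    out
  })
}
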