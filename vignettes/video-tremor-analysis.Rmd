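---
title: "Quantifying essential tremor from video: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying essential tremor from video: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tremorvid)
```

## The problem

Clinical rating scales for essential tremor (CRST, TETRAS) grade tremor by
eye on coarse ordinal scales. They saturate — on the CRST every postural
tremor above 4 cm scores the maximal 4 points — and they carry
test–retest and inter-rater variability. Markerless video motion analysis
replaces the eye with tracked coordinates: a camera films the upper limb
during a 60 s postural ("wing-beat") hold and a 15 cm line-drawing task,
anatomical points (fingertip, wrist, elbow, pen tip) are tracked frame by
frame, and the oscillation is summarised by a handful of kinematic
parameters. `tremorvid` implements that pipeline end to end — tracking,
kinematics, and the statistics used to validate such measurements — plus a
synthetic-data module that generates trajectories, rendered marker videos
and rated cohorts with known ground truth, so every stage can be tested
without any clinical recording.

## Tracking

Points are tracked by zero-normalized cross-correlation (NCC) template
matching: a square template is cut from the first frame around the selected
point, and each subsequent frame is searched within a configurable radius
of the previous position. Zero normalization makes the scores invariant to
global gain and offset changes of the video. The correlation peak is
refined to sub-pixel accuracy by separable three-point quadratic
interpolation. Frames whose best score falls below a threshold (default
0.5) are flagged *lost* and filled by linear interpolation from
neighbouring good frames; tracking aborts if more than a configurable
fraction (default 20%) of frames are lost. A slow exponential template
update is available but off by default: a fixed template cannot drift,
and on the rendered benchmark videos it recovers the generating trajectory
with RMSE well below 0.1 px.

Coordinates follow the screen convention — origin in the upper-left
corner, x rightward, y downward — and have no intrinsic physical scale;
`calibrate_scale()` converts px to mm from any object of known length in
the frame (the 15 cm line itself is a natural choice).

## Kinematic parameters

With positions in mm at frame rate `fps` (1/`fps` s between frames):

* displacement between consecutive frames: $d_i = \sqrt{\Delta x_i^2 + \Delta y_i^2}$;
* velocity: $v_i = d_i \cdot fps$;
* acceleration: $a_i = (v_{i+1} - v_i) \cdot fps$.

The per-task summaries are the mean velocity and the mean of the
*absolute* accelerations (signed accelerations average to nearly zero over
an oscillation and would carry no information).

**Analysis window.** For the postural task only the most severe stretch of
the recording is analysed: within the 5th–55th second the moment of
highest tremor amplitude is located as the maximum of a 1 s sliding
peak-to-peak envelope of the tremor signal, and a 10 s window is centred
on it (so the window always lies inside the 60 s recording). Numerical
ties — a constant-amplitude recording is all ties — resolve to the
earliest admissible centre. Both the window length and the search range
are configurable through `tremor_config()`.

**Tremor signal.** Frequency and amplitude are defined on a scalar
oscillation. The XY path is reduced to one dimension by removing a
centred *local-linear* baseline (1 s window; equivalent to a centred
moving average for linear trends but unbiased at the record edges, which
is why it is preferred to the plain moving average) and projecting onto
the first principal direction of the high-pass component. For the drawing
task the relevant oscillation is instead the deviation perpendicular to
the best-fit drawn line.

**Frequency** is the average number of waves per second. Complete cycles
are counted as positive-going zero crossings of the detrended signal
through a Schmitt trigger, and the frequency is the cycle count divided by
the time spanned by whole cycles, $f = (N-1)/(t_N - t_1)$ over the $N$
crossing events — algebraically "cycles per second", but measured over
complete cycles so that it does not jump in 0.1 Hz steps with the phase at
the window edges. The hysteresis band is
$h = \max\{\min(3\hat\sigma_d,\ 0.25\,\hat A),\ \text{floor}/2\}$, where
$\hat\sigma_d$ is a robust first-difference noise estimate and $\hat A$ a
robust half peak-to-peak. The cap matters: at 25 fps a 10 Hz tremor has
2.5 samples per cycle and its first differences are signal, not noise, so
an uncapped noise-scaled band would suppress genuine cycles. A signal
whose robust amplitude falls below the configurable amplitude floor
(default 0.5 mm, below clinically visible tremor) is flagged "no tremor"
and reported as 0 Hz.

**Amplitude** is the geometric mean of per-cycle peak-to-peak amplitudes,
cycles being delimited by consecutive positive-going crossings; cycles
below the noise floor (twice the hysteresis band) are excluded and
counted. The per-cycle amplitude estimator needs care at 25 fps: the raw
max–min of the 2–8 samples in a cycle misses the true peaks by up to tens
of percent near the Nyquist frequency. The default estimator therefore
fits each cycle by least squares with a local model
$c_0 + c_1 t + a\sin 2\pi f_k t + b\cos 2\pi f_k t$ (the trend term
absorbs local drift, which also sidesteps the slight passband attenuation
of the baseline filter — the fit runs on the raw projection, the
detrended signal being used only to delimit cycles) and reports
$2\sqrt{a^2+b^2}$. The cycle frequency $f_k$ starts from a five-cycle
running mean of the crossing intervals and is refined within ±6% by
minimising the residual sum of squares; single crossing intervals are too
noisy near Nyquist, and an unconstrained frequency search can wander into
a degenerate collinear regime on noisy cycles. `method = "sample_ptp"`
gives the naive sample excursion for comparison. On noiseless synthetic
tremor (3–10 Hz, 5–100 mm peak-to-peak, 25 fps) the default estimator
recovers the generating amplitude to well under 1% and the frequency to
under 0.01 Hz; with 0.3 mm observation noise, under 1% and 0.01 Hz
(verified in the test suite over a 50-seed ensemble).

**Cumulative length** (drawing task) is the summed frame displacement of
the pen tip over the drawing span, detected as the first-to-last sustained
motion above 5 mm/s for 0.2 s (both configurable, or the span can be given
explicitly). **Treatment change** of any positive parameter is
`log_change(T1, T2)` $= \log_{10}(T_2/T_1)$.

## Statistics

* **ICC(1,1)** (test–retest; one-way random effects, single measure) and
  **ICC(2,k)** (inter-rater; two-way random effects, average measure) are
  computed from the ANOVA mean squares, with 95% confidence intervals by
  the Shrout–Fleiss F-interval construction (Satterthwaite degrees of
  freedom and Spearman–Brown step-up for the average measure). Negative
  estimates are reported as computed. Categories: ≥0.90 excellent,
  ≥0.70 good, ≥0.50 moderate, ≥0.30 poor, otherwise very poor.
* **MDC95** = 1.96 × SDd (SD of paired test–retest differences) and
  **MDC%**: for a log10-transformed measure
  $100(1 - 10^{-1.96\,\mathrm{SDd}})$, the percent amplitude reduction
  just detectable against retest noise; for a rating scale the rating
  change converts to percent amplitude via the Weber–Fechner slope,
  $100(1 - 10^{-b \cdot 1.96\,\mathrm{SDd}})$. With the published
  test–retest inputs this reproduces the printed worked values: SDd
  0.211 → 61% for the postural video amplitude, SDd 0.408 with unit
  slope → 84% for TETRAS. The corresponding printed line-drawing cells
  (51% from SDd 0.056, and a negative SDd of −0.100 for CRST Part B) are
  not reproducible by any single formula consistent with the postural
  cells and are treated as unreliable, not emulated.
* **Spearman** rank correlation is the Pearson correlation of mid-ranks,
  p by the t approximation or exact permutation for n ≤ 9.
* **Wilcoxon signed-rank** drops zero differences, mid-ranks ties, and
  computes the exact two-sided p from the full distribution of the rank
  sum over all sign assignments (dynamic programming, so ties are exact)
  up to n = 25; beyond that a normal approximation with tie and
  continuity corrections. Two-sided exact p is
  $\min(1, 2\min(P(W\le w), P(W\ge w)))$.
* **Weber–Fechner fit**: ordinary least squares of log10 amplitude on
  rating. Because the regressor is a noisy, discretized perception of the
  response, the slope carries a small attenuation bias when rating noise
  is large relative to the rating spread; the simulation test keeps that
  bias inside the CI width by construction (fine-grained scale, modest
  noise).

## The synthetic-data generator

The generator defines the study conditions the package is validated
under. A trajectory is a quasi-sinusoid: carrier of given frequency and
peak-to-peak amplitude along an axis in the image plane, optional
per-cycle Gaussian frequency jitter, sinusoidal amplitude modulation,
linear baseline drift, and isotropic Gaussian observation noise. Defaults
(5 Hz, 20 mm peak-to-peak, 60 s at 25 fps) sit mid-range for moderate
essential tremor; validation ensembles span 3–10 Hz and 5–100 mm, the
amplitude span reported for surgical ET cohorts. The drawing generator
traverses a 150 mm segment at constant speed with tremor perpendicular to
it, tapered to zero over 0.3 s at the ends (the pen starts and finishes
on the dots), so the noise-free endpoints are exactly 150 mm apart. The
noise-free generating curve is attached to every trajectory as a closure,
giving tests an arc-length and envelope oracle. Rendered videos draw each
trajectory as an anti-aliased disc on a seed-fixed textured background
(lazily, one frame at a time, so 60 s of 720p video needs no significant
memory).

Cohorts draw true pre-treatment amplitudes lognormally (default median
14 mm, log10 SD 0.4, spanning roughly 2–90 mm), apply a mean 0.7 log10
(five-fold) treatment reduction with 0.15 log10 patient-level response
variability, and rate both visits through a noisy Weber–Fechner relation:
rating = the scale-clipped, grid-rounded inverse of
$\log_{10} A = a + b\,r$ plus Gaussian rating noise. The default anchors
follow CRST Part A (rating 2 ↔ 2 cm, rating 4 ↔ 4 cm ⇒ a = 1,
b = 0.15, integer grid 0–4); `rating_step = 0.5` gives TETRAS-like
scales. One consequence worth knowing: under a five-fold amplitude
reduction a 0–4 item saturates at its floor, so pre/post *change*
analyses in the tests use a composite tremor-score-like rating (0–32,
b = 0.06) that retains headroom, mirroring how change is analysed against
composite scores clinically — the 0–4 anchors remain the right default
for cross-sectional severity.

What the generator does *not* emulate: biomechanics (no limb model, no
harmonics), realistic hand appearance, occlusions or lighting changes in
video, rater-specific biases beyond additive noise, and depth motion (the
method is 2D by construction; out-of-plane tremor is underestimated).
Passing tests therefore demonstrate correctness of the algorithms under
quasi-sinusoidal planar tremor with Gaussian noise, not performance on
clinical footage.

## Numerical choices and degenerate inputs

* Seeded generators save and restore the caller's RNG state; identical
  spec + seed reproduce outputs bit for bit.
* Validation sizes: parameter recovery uses 50 seeds of 60 s / 25 fps
  recordings; tracking fidelity uses ten 60 s, 25 fps, 1280×720 videos
  (RMSE < 1 px against rendered ground truth); cohort structure uses a
  200-patient cohort checked against the analytic population Spearman
  correlation of the generator (numerical integration of the grade
  correlation) and 40-seed ensembles of 40-patient treated cohorts.
* Degenerate inputs fail loudly and specifically: invalid spec fields name
  the field; a constant trajectory yields a zero tremor signal (not an
  error) but an undefined amplitude; all-equal measurement matrices have
  undefined ICC; all-zero paired differences refuse the Wilcoxon test;
  coincident calibration points, markers leaving the rendered frame, and
  missing matrix cells each raise named errors.
* Subsampling artifacts: positions are continuous (sub-pixel); the
  rendered disc has a 1 px linear anti-aliasing ramp, which is what makes
  sub-pixel NCC interpolation effective.

## Known limitations

2D projection only; no spectral analysis (frequency is defined by cycle
counting, deliberately matching the waves-per-second definition rather
than a periodogram peak); the NCC tracker is single-hypothesis and will
follow the best local match, so it is not robust to occlusion beyond the
lost-frame interpolation; amplitude of strongly non-sinusoidal tremor is
reported as the fundamental's excursion under the default sine-fit
estimator. Ratings are simulated as noisy quantized perception of log
amplitude — real raters also weigh task performance, which is why rating
simulations should not be over-interpreted beyond the monotone-plus-noise
structure.
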