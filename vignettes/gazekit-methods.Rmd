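---
title: "gazekit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gazekit: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gazekit is an offline analysis stack for video-based eye tracking built on
the pupil/corneal-reflection principle, together with a synthetic-session
simulator that stands in for the camera and recorder hardware. This
vignette explains the models the package implements, the parameters that
matter, and the design decisions taken where the method leaves choices
open.

## The measurement model

A video eye tracker images the eye under infrared illumination. Two
features are extracted from each frame: the dark pupil and the bright
first-surface corneal reflection (the Purkinje image). The displacement of
the Purkinje image from the pupil center, the feature vector $(U, V)$ in
camera pixels, is approximately invariant to small head translations but
varies with eye rotation, which makes it a usable regressor for gaze
direction. Screen gaze is modelled as an affine function of the features:

$$ (X, Y) = (a_X U + b_X V + c_X,\; a_Y U + b_Y V + c_Y) $$

with $X$, $Y$ in degrees of visual angle. The six coefficients are
estimated from calibration data by minimising the summed squared distance
between predicted gaze and the fixated target. Because the objective
separates by axis, the optimum is two independent ordinary least-squares
regressions, solved exactly in closed form (`fit_calibration()`); there is
no iterative optimisation and no tolerance to choose. The fit is
identifiable from three non-collinear feature samples; in practice a
3 × 3 target grid (9.3° horizontal, 6.6° vertical spacing) is used, and a
session is conventionally accepted when the mean per-target error stays
below 0.8°.

Two temporal selection rules for calibration samples are provided, because
both are in use with moving targets (`select_calibration_samples()`):

* **exclusion**: discard samples within 200 ms before and after any target
  movement (the travel interval included). The target offset at the end of
  calibration is treated as a transition as well, which makes the two
  modes coincide exactly for jump schedules.
* **arrival**: keep only samples 200–800 ms after the target arrived.

The method does not say whether samples falling exactly on a window edge
are kept. gazekit excludes them: the kept region is an open interval.
This convention is arbitrary but must be fixed for exact tests.

## Image feature extraction

No specific pupil/glint algorithm is prescribed by the measurement model,
only its contract: produce sub-pixel centers or fail visibly. gazekit uses
the simplest method that meets the contract — double thresholding,
connected-component labelling (via EBImage), and intensity-weighted
sub-pixel centroids:

* pupil: largest connected component below `dark_threshold` whose area
  lies within `pupil_area_range`, centroid weighted by
  `dark_threshold − intensity` so the anti-aliased rim contributes
  fractionally;
* Purkinje image: brightest connected component above `bright_threshold`
  within `glint_roi_radius` of the pupil center (the glint physically sits
  on the cornea over the pupil), weighted by
  `intensity − bright_threshold`.

Ellipse fitting is deliberately out of scope; the centroid is accurate to
well under half a pixel on the rendered test images, including under pixel
noise with a standard deviation of 8 intensity levels, and is equivariant
to scene translation. Failure of either detector is encoded as
`ok = FALSE` and becomes a `valid = FALSE` sample downstream — tracking
loss is represented in-band and never interpolated.

## Filtering and velocity

Gaze traces are low-pass filtered with a zero-phase third-order
Butterworth filter, cutoff 60 Hz by default: the filter is applied
forward and then backward, so the net group delay is zero and the
effective magnitude response is the single-pass response squared. Zero
phase matters because saccade onsets are read off the filtered velocity;
a causal filter would shift them.

Numerical choices:

* The forward–backward pass uses odd-reflection padding of length
  3 × (order + 1) with steady-state initial conditions, implemented in
  compiled code. This is the standard transient-minimising scheme; the
  method itself is silent on edge handling.
* Valid segments shorter than 3 × (order + 1) samples pass through
  unfiltered and are flagged; gaps are never bridged, because
  interpolating through blinks or tracking loss would fabricate data.
* At a 120 Hz sampling rate the 60 Hz cutoff equals the Nyquist
  frequency, so filtering is skipped (the data contain no removable
  components); `detect_events(filter = "auto")` applies this rule.
* Speed is estimated by central differences on the *actual* timestamps —
  recorded intersample intervals jitter, and using the nominal rate would
  bias velocities — with one-sided differences at segment endpoints.

The expected attenuation of a pure sine under the zero-phase pass is the
squared magnitude of the bilinear-transform Butterworth,
$|H|^2 = 1/(1 + (\tan(\pi f/f_s)/\tan(\pi f_c/f_s))^{2\,\mathrm{order}})$;
tests verify the implementation against this closed form rather than
against another filtering routine.

## Saccade and fixation detection

Detection is the classic three-parameter velocity-threshold procedure
(`detect_events()`):

1. samples with speed strictly above `velocity_threshold` (default
   22 °/s) form maximal supra-threshold runs;
2. runs spanning at least `min_saccade_ms` (default 12 ms, measured from
   first to last supra-threshold sample) are saccade candidates;
3. successive candidates separated by less than `min_fixation_ms`
   (default 12 ms) are merged, spanning first onset to last offset;
4. surviving candidates are saccades; the complementary intervals are
   fixations. The two event types tile the analysed span exactly.

Conventions fixed here because the procedure leaves them open: strict
`>` threshold comparison; a run's onset is the time of its first
supra-threshold sample; a merged saccade's amplitude uses the positions at
the merged onset and offset (consistent with the start/end definition);
`min_fixation_ms` acts only as the merge criterion and does not suppress
short terminal fixations. Events whose span touches invalid samples are
kept but flagged `unreliable`, and trial classification treats a flagged
first saccade as a detection failure — onset detection inside a
tracking-loss gap cannot be trusted. A single left-to-right merge pass is
provably equivalent to iterating to a fixed point, because merging two
candidates never changes the surviving gaps; the test suite checks the
whole detector against a literal, unoptimised reference implementation on
every supra-threshold pattern up to length 12 and on 10,000 random longer
ones.

The defaults (22 °/s, 12 ms, 12 ms) suit 120–500 Hz video data. Note that
at 120 Hz a 12 ms minimum duration requires three supra-threshold samples,
so small-amplitude saccades near 2° sit close to the detection limit —
recovery there relies on the central-difference speed estimate widening
the supra-threshold window by roughly one sample on each side.

## Trial-level analysis

For saccade tasks, the first saccade with onset at or after target onset
(closed boundary) is the response. A trial is valid when that saccade
exists, is not gap-flagged, has latency within the closed window
100–600 ms, and lands within 2.0° of the expected position — the target
for prosaccades, the mirror of the target about fixation for
antisaccades. Each invalid trial carries exactly one rejection reason,
checked in the order `no_saccade`, `detection_gap`,
`latency_out_of_range`, `landing_too_far`. Spatial accuracy for
fixation-style tasks is the mean distance between gaze and target over
the open window 250–750 ms after each target jump, i.e. after the
orienting saccade has landed and before the next jump.

Task summaries (`summarize_task()`) average valid trials only. A
consequence worth stating explicitly: when latencies are generated from a
truncated normal distribution and then filtered by the 100–600 ms
validity window, the estimand of the per-condition mean is the mean of
the *doubly truncated* distribution, not the nominal location parameter.
For a gap condition with nominal mean 150 ms and SD 50 ms the valid-trial
mean is ≈ 164 ms. The recovery tests compare against this analytic
truncated mean; comparing against the nominal parameter would build a
known bias into the oracle.

## The simulator

`simulate_session()` generates complete sessions with known ground truth
for every injected saccade, so every downstream module can be validated
end to end. What it emulates, with defaults chosen as the study
conditions of the tasks it mimics:

* **Tasks.** Antisaccade (4 directions, balanced within 20-trial blocks;
  prosaccade and antisaccade blocks alternate), gap/overlap (left/right
  targets, gap durations −200…200 ms balanced within blocks; negative
  values mean the fixation point goes off before target onset), and a
  6 × 6 grid accuracy task with 2.7° spacing and ten 1-second target
  jumps per trial. Target eccentricity defaults to 4.2°; fixation
  durations are drawn from 1000–1500 ms in 100 ms steps.
* **Kinematics.** Raised-cosine velocity profiles with the linear
  main-sequence rule $D = 20\,\mathrm{ms} + 2\,\mathrm{ms/°} \times$
  amplitude; peak velocity is analytically $2A/D$. This is a smooth,
  standard approximation — real saccades are mildly asymmetric, which the
  simulator does not reproduce.
* **Latencies.** Truncated normal on [80, 700] ms. Defaults: gap/overlap
  means (150, 175, 200, 230, 260) ms for gaps (−200, −100, 0, 100,
  200) ms; prosaccade 200 ms, antisaccade 270 ms; grid task 150 ms (the
  jumps are temporally predictable). SDs are 50 ms (20 ms for the grid
  task), the typical human range. The [80, 700] support deliberately
  spills over both sides of the 100–600 ms validity window so the
  rejection paths are exercised.
* **Noise and timing.** Isotropic Gaussian positional noise (default SD
  0.1°) on every sample; landing scatter SD 0.3°; intersample-interval
  jitter $\Delta t = \Delta + \mathcal N(0, \sigma_j)$ truncated at
  $0.1\Delta$ (jitter is modelled on intervals, so the interval SD equals
  the jitter parameter); i.i.d. frame drops; tracking loss as a two-state
  Markov process emitting contiguous `valid = FALSE` runs.
* **Images.** Frames render a fixed pupil and a glint displaced by
  $(U, V)$, with seeded pixel noise, closing the loop through
  `extract_features()`.

Everything is deterministic given the seed: identical configurations
produce bit-identical CSV files. What the simulator does *not* emulate —
and what passing tests therefore do not establish about real recordings —
includes pupil-size dynamics, smooth pursuit, corrective saccades and
post-saccadic oscillations, eyelid occlusion, head movement, and
non-Gaussian camera noise.

## Problem sizes and numerical conventions in the validation suite

The recovery checks run at desk scale, chosen to keep sampling error
comfortably below the asserted tolerances: 50 random models for exact
calibration recovery; ~18,000 supra-threshold patterns for detector
equivalence; 200 simulated trials per sampling rate (120/250/400/500 Hz)
for detection recovery; 20 seeds × 400 trials at 250 Hz for gap/overlap
structure recovery; ~10⁵ window samples for the spatial-error closed form
(mean error $\sigma\sqrt{\pi/2}$ under isotropic noise); 50 rendered eye
poses for imaging recovery. Percentiles use linear interpolation between
order statistics (R type 7). Recording CSVs print floats with 17
significant digits so finite values round-trip bit-exactly.

## Known limitations

* The linear gaze model ignores optical distortions that a quadratic or
  homography calibration would absorb; accuracy degrades toward the
  screen corners on real hardware.
* Centroid-based pupil detection is biased by partial eyelid occlusion
  and by the glint "hole" it punches into the pupil mask (sub-0.15 px for
  the rendered geometry, but potentially larger on real images).
* Velocity-threshold detection cannot separate glissades or
  post-saccadic oscillations from saccades, and the 12 ms duration gate
  limits sensitivity to microsaccades; both are out of scope.
* The latency estimator inherits a small positive bias (≈ 2 ms at
  250 Hz) from threshold crossing and sample quantisation; it is well
  inside the statistical tolerance of the recovery tests but would matter
  for absolute latency claims at millisecond precision.
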