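---
title: "Methods: equine spinal kinematics and their variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: equine spinal kinematics and their variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and numerical choices
behind `spinekin`: how marker trajectories become angle time series, how
strides become measurement means, and how the repeated-measures statistics
are defined. It also states what the synthetic-data generator does and does
not emulate, so that the meaning of a passing test suite is clear.

## 1. From markers to angles

### Coordinate conventions

Positions are in millimetres in a right-handed world frame with the
vertical axis up (+z). A trial is a `marker_series`: one n×3 matrix per
marker plus a per-frame gap mask. Untracked frames are never interpolated;
they are carried as `NA` and any stride touching a gap in a needed marker
is dropped. (Filtering and heading estimation internally bridge gaps by
linear interpolation for numerical stability only — the bridged frames are
re-masked immediately afterwards.)

### Filtering

All marker coordinates pass a 4th-order digital Butterworth low-pass,
applied forward and backward (`lowpass_filter()`), default cut-off 30 Hz at
100 Hz sampling. Zero-phase filtering is used because a one-directional
pass would delay the signal by several frames and bias stride timing; the
price is that the effective magnitude response is the squared single-pass
response, which the tests verify against the closed-form prewarped
(bilinear-transform) Butterworth magnitude. The filter pads each signal
with odd-reflected copies (up to 100 samples) before the forward-backward
pass; without this the zero-initial-condition transient of the recursive
filter contaminates roughly the first quarter second of every trial.

### The heading frame and body lean

All planes are built from an instantaneous *heading frame*: x̂ is the unit
smoothed horizontal velocity of the tuber sacrale marker, ẑ is vertical,
ŷ = ẑ × x̂ points left. Velocity is the slope of a centred moving linear
regression over 0.5 s — long enough to suppress the within-stride
oscillation of the sacrum track, short enough to follow a 10 m lunge
circle. A heading-based frame (rather than a lab-fixed one) is the only
definition that treats straight lines and circles uniformly; it also makes
every angle invariant to rigid rotations of the capture volume, which the
tests check.

On the circle the horse leans inward, so an upright frame would mix roll
into the other projection angles. The body-lean angle is estimated as the
stride-mean pelvic roll over all complete strides and the frame's ŷ/ẑ axes
are rotated about x̂ by that angle (`lean_correct()`); after correction the
stride-mean pelvic roll is zero by construction (the tests require
< 0.1° on simulated leaning trot). The default lean in the circle
simulator is the banking angle atan(v²/(g·r)), ≈ 13° at 3.3 m/s on a
4.85 m radius — the physically neutral choice.

### Angle definitions

- *Back angles* (`back_angle()`): deviation from collinearity of two
  projected segments, 0 = straight. Whole-back flexion–extension and
  lateral bending use withers–T15 and T15–tuber sacrale in the sagittal
  and dorsal plane; each segmental angle uses the markers immediately
  cranial and caudal (e.g. T15 from T12–T15 and T15–T18). The sign is
  positive with the apex below the chord (sagittal) or left of it
  (dorsal); ROM is sign-free, so this choice only affects plots. The
  withers anchor of the whole-back angle is the central withers marker.
- *Pelvic angles* (`pelvic_angles()`): roll is the angle of the
  left-to-right tubera coxae line in the frontal plane (positive =
  right side down), pitch the tuber sacrale → coxae-midpoint vector in
  the sagittal plane (it carries a constant anatomical inclination that
  cancels in ROM), yaw the coxae line in the dorsal plane. These are the
  only projection angles available from the three pelvis markers.
- *Body tracking* (`body_tracking_angle()`): horizontal angle between the
  pelvis→withers direction and the velocity direction, positive =
  forehand right of travel.
- *Head swivel* (`head_swivel_angle()`): horizontal angle between
  head→withers and withers→pelvis, positive = cervical bending right.
- *Speed*: magnitude of the smoothed horizontal velocity of the tuber
  sacrale, in m/s.

All angles are reported in degrees in (−180, 180].

## 2. Strides and measurement means

At trot the sacrum reaches a vertical minimum twice per stride. Stride
boundaries are the low-pass-filtered (10 Hz) sacrum minima at which pelvic
roll — one cycle per stride — is increasing, so each interval spans exactly
one stride; if the roll signal carries no oscillation (degenerate input)
every second minimum is taken instead. Minima above the signal median are
ignored, and intervals shorter than 0.55× or longer than 1.8× the median
duration (missed/doubled events) are dropped. Absence of oscillation yields
zero strides, not an error.

Per stride, ROM-type parameters are max − min and signed parameters (head
swivel, body tracking, speed) are means; a measurement mean averages over
complete strides, with stride frequency = 1/mean duration. Following
standard quality practice for over-ground trot-ups, a measurement with
five or fewer complete strides is discarded (`min_strides = 6`,
configurable); "five or fewer" rather than "fewer than five" is adopted as
the stricter of the two readings. The realised lunge circle diameter is
twice the radius of an algebraic (Kåsa) least-squares circle fit to the
horizontal sacrum track, requiring at least half a revolution.

## 3. Statistics

### Percentiles

`percentile_summary()` pools measurement means over horses and repetitions
per path–surface condition and reports the 5%, 50% and 95% quantiles with
linear interpolation of order statistics (R's default type 7; the exact
rule is configurable and matters only in the far tails of small samples).

### The variability model

To isolate *between-measurement* variation from between-horse differences,
each horse's measurement means are centred within each horse × path ×
surface cell: d = value − mean(M1–M12). Absolute deviations are
right-skewed, so the model response is y = √|d|. The model is

y ~ day + rep_index + path + surface (+ speed) + (1 | horse), REML

with day a 3-level factor (day 1 reference), `rep_index` the numeric
within-day repetition (1–5; 1–2 at the recheck), path (straight reference)
and surface (soft reference). Day and raw measurement number (1–12) would
be aliased as factors; the day-factor + numeric-repetition coding keeps
both the day contrast and the repetition trend estimable, which is exactly
the structure of interest (habituated horses vary less over repetitions;
rechecks weeks later vary more). Interactions are not estimable because
circles are never trotted on hard surface, and models are not reduced.
Wald t tests use Satterthwaite denominator degrees of freedom (a
z-approximation is available). Factors constant in the data (e.g. a
single-condition subset) are dropped with a message rather than producing
a singular design; genuinely aliased designs raise an error naming the
aliased columns.

The 95% prediction upper limit per condition is computed marginally on the
transformed scale, x'β̂ + z₀.₉₇₅·√(σ̂²_horse + σ̂²_resid), with x encoding
the condition at the reference day and the mean repetition index, and is
back-transformed by squaring. This is the simplest defensible construction
given that deviations are zero-centred (so only the upper limit is
informative); no retransformation bias correction is applied, and the
Monte-Carlo oracle in the test suite shows the construction tracks the
empirical 97.5th percentile of |d| to within a few percent on half-normal
deviations. A Student-t quantile can be substituted for z.

### Repeatability

ICC(1) per parameter and condition from `value ~ 1 + (1 | horse)` fitted
by REML: ICC = σ²_horse/(σ²_horse + σ²_resid). One-way ICC is the
appropriate form for a single grouping factor per condition. REML was
chosen over ML; on balanced data the estimate coincides with the ANOVA
closed form (MSB − MSW)/(MSB + (k−1)·MSW), which the tests require to
3 decimals. Boundary fits (between-horse variance estimated at zero) are
reported as 0 and flagged; cells without at least two horses with two
repetitions are marked unavailable.

## 4. The synthetic-data generator

`simulate_trot_markers()` is *kinematic*: angle waveforms are prescribed,
not produced by a musculoskeletal model. This is deliberate — the pipeline
measures kinematics only, so prescribed waveforms give exact ground truth
for parameter-recovery testing ("generator–analyzer closure"). The phase
structure is that of trot: vertical displacement and flexion–extension at
twice stride frequency, lateral bending, pelvic roll and yaw at stride
frequency. The whole-back apex offset is constructed so the *measured*
whole-back angle equals the prescribed sinusoid (the linearised chord
construction is exact to ≪ 0.1% at physiological amplitudes); remaining
spinous markers follow a half-sine bending shape; the pelvis is a rigid
rotated body. Default amplitudes, stride frequency (1.34 Hz), speed
(3.79 m/s) and stride count (14) are set to measurement-median magnitudes
typical of sound trotting warmbloods, and the default marker noise of
3.2 mm per coordinate mirrors a typical optical-capture calibration
residual.

What the generator does *not* emulate: soft-tissue artefact (its noise is
white, which inflates extremum-based ROM more than correlated soft-tissue
motion does — visible as the difference between noisy and noise-free
recovered ROM), hoof-impact transients, genuinely curved-spine postures on
the circle (markers ride the arc, so the simulated body tracking on the
lunge reflects chord geometry rather than a horse's haunches-in tendency),
asymmetric or lame gaits, and marker drop-out (tests introduce gaps
explicitly). Passing closure tests therefore demonstrates that the
*pipeline* is correct, not that real horses look like the simulator.

`simulate_measurement_dataset()` draws measurement means directly:
condition mean + horse effect N(0, σ²_horse) + day effect + repetition
trend + N(0, σ²_resid), on the 5+5+2 schedule over three days and four
conditions, with horses 3, 8 and 10 absent at the recheck by default (a
realistic drop-out pattern). Defaults put substantially more variation
between than within horses (e.g. whole-back flexion–extension
σ_horse = 0.5°, σ_resid = 0.35°) and add one residual-sd of extra recheck
deviation. Two repetition-trend knobs exist because they answer different
questions: `rep_slope` shifts the *mean* linearly over repetitions, while
`rep_sd_slope` scales the *residual sd* (default −0.05 per repetition) —
only the latter expresses "horses vary less as they habituate", which is
what the variability model's repetition coefficient measures.

## 5. Numerical choices and degenerate inputs

- Quantile rule: type 7 (configurable). Prediction-limit quantile: normal
  (Student-t optional). Significance threshold 0.05.
- Degenerate projections (vector orthogonal to a plane), zero-length body
  segments, stationary tracks and straight tracks fed to the circle fit
  raise informative errors; constant signals yield empty segmentations;
  constant model responses yield exact zero variance components without
  calling the mixed-model machinery.
- Negative prediction limits on the transformed scale are truncated at 0
  before squaring; ICC estimates are reported in [0, 1].
- The TSV trajectory dialect (`write_trajectories()`) is a defined
  convention of this package: a `sampling_rate` header line, then
  `<label>_X/_Y/_Z` columns, `NA` for untracked frames.

## 6. Problem sizes in the test suite

The suite runs entirely on synthetic data: single trials of 6–24 strides
(600–2000 frames at 100 Hz), study datasets of 12 horses × 12 measurements
× 4 conditions, 200 replicates for ICC recovery, 10 replicate datasets for
the prediction-limit Monte-Carlo comparison, and 1000 simulations for the
type-I-error calibration of the fixed-effect tests (8 horses × 12
measurements each). These sizes keep every check well-powered while the
whole suite completes in a few minutes on one core.

## 7. Known limitations

- C3D containers are not read; trajectories must be exported to the TSV
  dialect (or constructed in R).
- The whole-back angle treats the back as a single joint at T15; segmental
  angles recover more spatial detail but are noisier in practice because
  their lever arms are short — the same reason their repeatability is
  lower in real data.
- The prediction-limit construction is marginal (fixed-effects mean plus
  total variance); it does not condition on a horse, and the square-root
  back-transform is applied without bias correction.
- Sign conventions for roll and the back angles are package conventions;
  only body tracking and head swivel have field-standard signs (positive =
  right).
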