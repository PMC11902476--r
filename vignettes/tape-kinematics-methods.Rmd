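---
title: "Methods: estimating tape kinematics from anchor-point angles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating tape kinematics from anchor-point angles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tapekin)
```

## The model

Balance-training devices with tape-like unstable bases (slacklines, the
two tapes of a Sensopro Luna) share a constraint that makes their
kinematics observable from the ends alone: the tape carries only
longitudinal tension, so each unloaded stretch of tape is a straight
segment between its anchor and the load point. Measuring the orientation
of the tape sections adjacent to the two anchors therefore determines
where the load is, without instrumenting the foot or the middle of the
tape.

The device frame has its origin mid-span, X forward along the tape, Y
left, Z up; the anchors of the reference device sit at (±863, 0, 0) mm
(span `L = 1726` mm). With normalized pitch angles α (back) and β
(front), both positive when the tape is displaced downward, the loaded
point follows from intersecting the two anchor rays:

$$t = \cos\alpha + \frac{\sin\alpha\,\cos\beta}{\sin\beta},\qquad
  Z = -\frac{\sin(\alpha)\,L}{t},\qquad X_Z = \frac{\cos(\alpha)\,L}{t},$$

with $X_Z$ the distance from the back anchor. An algebraically equivalent
trigonometric form, $Z = -L/(1/\tan\alpha + 1/\tan\beta)$,
$X_Z = |Z|/\tan\alpha$, is implemented as well; `estimate_sagittal()`
exposes both through its `method` argument, and the test suite sweeps
both over $(\alpha,\beta) \in [0.1°, 80°]^2$ asserting agreement to
$10^{-9}L$. The same mathematics applied to the yaw angles in the
horizontal plane gives the lateral displacement Y and a second,
independent longitudinal estimate $X_Y$ (`estimate_transversal()`).

### Which anchor carries α

The model is symmetric: binding α to the front instead of the back anchor
only mirrors X about mid-span. This package fixes α = back anchor
(x = −L/2), so device-frame x equals $X_Z - L/2$. This is a documented
constant, not a tunable.

### Flat-foot correction

A foot is not a point mass. For a horizontal flat contact segment of
length $L_F$, similar triangles (intercept theorem) give the ratio of the
true lowest-point depth $d_R$ to the ray-intersection depth $d_M$ as

$$d_R / d_M = 1 - L_F / L,$$

independent of where the segment sits along the span. For $L_F = 260$ mm
on $L = 1726$ mm the ratio is 0.8494 ≈ 0.85, the package default for
`segment_ratio`. Note a subtlety: the construction is sometimes quoted as
$d_R/d_M = L_F/L$, which cannot reproduce the stated 0.85 for these
dimensions; the geometry unambiguously gives $1 - L_F/L$, and the
forward simulator reproduces it to $10^{-9}$ (acceptance test 1).
Only Z is corrected; the X prediction is unaffected by this
parameterization. The ratio is exposed as a calibratable parameter
because in practice it depends on shoe size and stiffness; data-fitted
values for a particular population (e.g. 0.82 instead of 0.85) can be
obtained with `calibrate_params()` and are deliberately not shipped as
constants.

### Roll variants

The twist of the tape increases roughly linearly from each anchor toward
the foot, but the spring segments at the ends twist at a different rate
than the canvas. The textual definitions of the four variants leave the
exact functional forms open; the implementations here are the minimal
reconstructions consistent with them:

* **RM** — constant twist rate from anchor to foot. The measured section
  roll is attributed to the inner boundary of the instrumented section
  (distance `s` from the anchor), each per-anchor estimate is
  `roll · d/s`, and RM is their mean.
* **RS** — the spring (length $L_s$) twists at `k` times the tape rate
  and the sensor section lies within the spring, so each estimate is
  `roll · (k L_s + (d − L_s)) / (k L_s)`; RS is the mean. With `k = 1`
  and `s = L_s` (the default geometry) RS reduces to RM.
* **RWS** — the RS per-anchor estimates with linear position weights
  `w_back = (L − d_back)/L`, `w_front = 1 − w_back`, so the sensor nearer
  the foot dominates. Linear weights are the minimal choice satisfying
  that description.
* **RA** — the plain sum of the two measured rolls; a heuristic that
  ignores the geometry (and therefore has nonzero error even in a
  noise-free simulated world; the tests assert this).

No value of `k` is published for any device; the shipped default `k = 1`
(with RS collapsing to RM) is deliberate, and `calibrate_params()`
estimates `k` from roll-only manipulation recordings. Both calibration
problems reduce to through-origin least squares: depth regression for
`segment_ratio`, and a regression linear in `1/k` for `spring_coeff`.

### Guards and degenerate inputs

* Small-angle guard: inputs with `min(|angle|)` **strictly** below 0.1°
  default to zero predictions (no displacement, X at mid-span), per
  plane. The tie at exactly 0.1° computes normally ("less than").
* Opposite-sign angle pairs mean the rays do not intersect below the
  tape — an unloaded or oscillating state. The low-level estimators flag
  these frames (`no_intersection`) and return `NA` rather than
  extrapolate; the stream-level driver `estimate_tape()` substitutes the
  zero default so that summaries stay computable, with the flag kept.
  `allow_negative = TRUE` evaluates the raw closed form anyway, which is
  numerically unstable by design and exists to reproduce the behaviour
  of uncorrected drifting IMU input.
* Angles at or beyond 90° are input errors, not flags.

## The synthetic world

No public dataset of raw trials exists, so the package carries a forward
geometric simulator (`simulate_static()`, `simulate_trial()`) that is
both the synthetic-data generator and the oracle for the inverse model.
Its stated world:

* Geometry: span 1726 mm, spring length 200 mm, sensor sections ending
  at the spring boundary, 200 mm tape width (`luna_geometry()`).
* An ideal rope: straight segments from each anchor to the contact, a
  horizontal flat segment for a flat foot (roll applied as a rigid
  rotation of that segment about the tape axis), no catenary sag, no
  dynamics, no mass. Depth maps monotonically to both anchor angles.
* Torsion piecewise linear, with the spring twisting at `spring_coeff`
  times the tape rate; lateral geometry optionally gets an analogous
  spring multiplier (`yaw_multiplier`, default 1 because no value is
  published; values > 1 reproduce the observation that yaw is larger in
  the anchor-adjacent segments).
* Keyframe interpolation is monotone cubic (`monoH.FC`) so interpolated
  depths never overshoot below zero; airborne transitions are step
  changes.
* IMU degradation (`add_imu_drift()`): white noise of σ = 0.1° on all
  channels, a deterministic one-sided pitch ramp of −0.05°/s (−3° over a
  60 s trial, a visible but not catastrophic drift), an unbiased yaw
  random walk of 0.02°/√s, and no roll drift. The magnitudes are not
  published anywhere; these defaults were chosen once as plausible for
  consumer sensor-fusion output and are configurable. The drift model is
  phenomenological — the package deliberately does not re-derive any
  sensor-fusion algorithm.

What a green test does establish: the inverse model exactly inverts the
geometry it assumes (round trips to $10^{-6}$ mm over the load space),
parameters are recoverable from single-mode calibration recordings at
realistic noise, and drift corrections act in the documented direction
(IMU worse than motion capture; clamping strictly reduces X and Z RMSE).
What it does not establish: accuracy on real recordings, where tape
bending around the shoe, marker placement error, and sensor-fusion
artifacts add error sources the simulator does not model. The published
per-exercise RMSE tables are not reproducible without the undeposited
raw data and are out of scope.

## Marker sections and rigid reconstruction

The motion-capture layer tracks eleven markers per tape (six outer-edge,
five inner-edge, with the center inner marker shared between the two
central marker pairs), defining seven sections; the back and front
sections connect their two tape markers to the anchor coordinates, which
come from the device configuration, not from frame markers. The exact
longitudinal stations of the pairs are not published; the default layout
spaces the six interior stations evenly, which preserves every checkable
property (marker counts, three markers in the middle section, four
elsewhere, anchor-connected end sections).

Per-section rotations are recovered with the Kabsch algorithm
(`kabsch_transform()`, proper rotation via SVD sign correction) against
the per-trial rest pose, then decomposed as Tait-Bryan XYZ-intrinsic
angles (`taitbryan_xyz()`), which round-trip through recomposition to
machine precision and flag gimbal proximity. Within the device's
restricted rotation range these angles stay within 5% of the axis-angle
magnitude (tested), which is what justifies using them at all.

Simulated markers are mapped rigidly onto their straight piece of tape,
with the along-piece stretch the rope geometry implies. A useful
property of the symmetric layout is that this stretch is axis-aligned in
the Kabsch bases, so the recovered rotation is *exact* (the fit RMSD is
nonzero, the angles are not biased) for any section whose markers lie on
one straight piece with constant twist. Sections whose marker set spans
the foot contact — including the three central sections, which share the
center marker — are only approximately rigid, on the simulator exactly as
on the physical tape. The tests therefore assert machine-precision
recovery for the pure sections and bounded error near the contact.

## Signal conditioning

All filtering is offline, zero-phase (forward-backward), because the
pipeline processes recordings, not live streams; the effective order
doubles. Real-time causal variants are out of scope.

* Low-pass: third-order 100 Hz Butterworth before resampling.
* Resampling: linear interpolation onto a shared 200 Hz grid over the
  overlap of the two streams. Linear is deliberate — no overshoot at
  airborne discontinuities.
* Exclusion: frames with the foot center **at least** 70 mm above the
  tape center are excluded (inclusive comparison), as are
  both-feet-on-one-tape frames; masks never alter values.
* Drift adjustment: two modes are exposed because the source material
  describes both without choosing — `clamp` (negative normalized pitch
  set to zero; positive samples untouched) and `shift` (whole series
  raised so its minimum is zero). Neither is presumed canonical;
  `clamp` is the default in the CLI.
* Detrending: third-order high-pass Butterworth, 0.001 Hz preset for
  pitch and 0.01 Hz for roll. The trade-off — genuine slow changes in
  movement patterns are attenuated along with the drift — is inherited
  by design.

No Butterworth/filtfilt implementation exists in the available R stack,
so the package implements the bilinear-transform design in second-order
sections with steady-state initial conditions and odd edge extension.
Second-order sections matter here: at 0.001 Hz cutoff on a 200 Hz
stream, a single-polynomial transfer function is numerically unusable.
The design is pinned against an independent reference implementation in
the test suite (frozen coefficient sets and filtered fixtures; interior
samples agree to ~1e-12 for the low-pass case). For cutoffs whose time
constant is comparable to the record length, edge handling dominates any
implementation's output; variance-preservation tests therefore use
records long relative to the cutoff period.

## Evaluation conventions

* RMSE per trial and output over non-excluded frames.
* Box statistics: percentiles {2, 25, 50, 75, 98} with linear
  interpolation between order statistics (R `type = 7`; the choice is a
  documented convention, not published). Values outside [p2, p98] count
  as outliers. Percentiles only — no normality assumption is made when
  quoting 96% intervals.
* Position-conditioned profiles: per-bin percentile sets against
  reference X or Z; empty bins are reported as gaps.
* Reference extraction: Y and Z from the section with maximum |Z|, roll
  from the section with maximum |roll| (possibly a different section),
  X from the foot-marker centroid; argmax ties break to the lower
  section index for determinism.

## Known limitations

* The spring length shortens under load; the factor relating measured
  roll to foot roll therefore drifts slightly with pitch. Not modeled.
* The yaw-based $X_Y$ estimate is intrinsically ill-conditioned on
  devices with small lateral range; it is retained because the
  XZ-vs-XY discrepancy is a useful reliability flag
  (`quality_flags()`), not because it is a good position estimate.
* Opposite-sign inputs and free tape oscillation after lift-off are
  detected, not modeled.
* No center-of-pressure inference, no foot pitch/yaw estimation, no
  slackline- or trampoline-specific parameterizations.
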