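---
title: "Quantifying repetitive arm movement from arm-worn inertial sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying repetitive arm movement from arm-worn inertial sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(armkit)
```

## The problem

Manual wheelchair users load their shoulders for both locomotion and
activities of daily living, and repetitive arm motion — especially at
elevated postures — is a recognised extrinsic risk factor for rotator cuff
pathology. Quantifying that exposure outside the laboratory requires an
instrument that works from body-worn sensors alone, over full days, without
video or supervision.

`armkit` implements such an instrument. From the raw accelerometer and
gyroscope streams of an arm-worn inertial measurement unit (IMU) it
produces, in order:

1. a drift-free **humeral elevation angle** trace $\phi(t) \in [0°, 180°]$
   (0° = arm hanging along gravity, 180° = overhead);
2. **movement cycles**: an elevation of at least a movement threshold
   followed by a lowering of at least the threshold;
3. **active and resting bouts**: runs of cycles whose no-activity gaps are
   at most 7 s, separated by rests strictly longer than 7 s;
4. a set of **exposure metrics** (bout counts, durations, cycles per bout,
   per-bout median and peak elevation), reported for all active bouts and
   for the stratum of bouts longer than 10 s;
5. validation scores against video-rated intervals, and paired
   dominant-vs-non-dominant Wilcoxon comparisons.

A synthetic-data generator produces elevation traces and raw IMU streams
with exact ground truth, so every stage is testable without any recorded
data.

## Elevation angle: model and assumptions

Let $R(t)$ be the sensor-to-world rotation and $\hat u$ the humeral
long-axis reference expressed in the sensor frame. The elevation angle is

$$\phi(t) = \arccos\!\big(\langle R(t)\,\hat u,\; \hat z_w\rangle\big),$$

where $\hat z_w$ is world up and $\hat u$ is calibrated as the mean
specific-force (anti-gravity) direction during a quasi-static arm hang.
Because $\phi$ depends only on the direction of gravity relative to the
segment, it is insensitive to heading drift — the quantity that cannot be
estimated without a magnetometer. `armkit` deliberately uses no
magnetometer (free-living magnetic fields are non-uniform), so heading
carries **no accuracy contract** and plane-of-elevation /
humerothoracic angles are out of scope: shoulder flexion and abduction are
indistinguishable and both appear as elevation.

Orientation itself comes from a quaternion complementary filter
(`fuse_orientation()`): exact per-step quaternion-exponential propagation of
the trapezoidally averaged gyroscope rate, plus a small rotation of the
estimate toward the measured specific-force direction each sample. The
per-sample gain (default `0.02`, dimensionless) trades gyro drift
suppression against accelerometer noise: at 50 Hz the steady-state
inclination error from accelerometer noise of SD $\sigma_a$ is roughly
$\sqrt{g/(2-g)}\,\sigma_a/9.81$ rad for gain $g$, about 0.3° at
$\sigma_a = 0.5\ \mathrm{m/s^2}$. Any filter meeting the
drift-free-inclination contract would be equally valid; the contract, not
the filter, is what the tests pin down (end-to-end recovery RMSE < 0.5°
noiseless, < 2° at $\sigma_a = 0.5\ \mathrm{m/s^2}$,
$\sigma_g = 0.005\ \mathrm{rad/s}$).

**Calibration** is operationalised as a ≥ 1 s static arm hang (mean gyro
magnitude < 0.05 rad/s). The only anatomical quantity needed downstream is
the long axis relative to gravity, which this posture determines directly;
the original multi-posture functional-calibration protocols do more, but
nothing the elevation angle uses.

## Cycle detection

The paper-level definition — "an elevation greater than a movement
threshold followed by a lowering greater than the threshold, with
sub-threshold motion in between treated as idle time belonging to the
cycle" — is operationalised as follows (`detect_cycles()`):

1. **Turning points.** The alternating minima/maxima of the (smoothed)
   trace, endpoints included, plateaus collapsed to their first sample
   (`extract_turning_points()`).
2. **Pruning.** While any adjacent extremum pair spans less than the
   threshold, delete the pair with the smallest absolute range (leftmost on
   ties). A sub-threshold pair that includes the first or last extremum of
   the series drops only that endpoint. The survivors alternate and every
   adjacent range is ≥ threshold.
3. **Cycles.** Every surviving *interior* maximum is one cycle. Endpoint
   maxima are not cycles: an elevation at the end of a recording with no
   subsequent lowering (or the mirror case) lacks one of the two required
   events.
4. **Anchoring.** Within the raw trace, the cycle start is the last sample
   before the peak at which the angle is within `idle_band_deg` (default
   2°) of the preceding valley value, and the end is the first such sample
   after the peak with respect to the following valley. Without this band,
   consecutive cycles separated by long rests would share valley extrema
   and rests would be unmeasurable. The anchoring limit is additionally
   capped at `peak - threshold`, which guarantees the per-cycle invariant
   `rise_deg >= threshold` and `fall_deg >= threshold` even for marginal
   cycles whose range is between the threshold and threshold + band.

The pruning order (smallest range first, leftmost on ties) and the
single-endpoint rule are design choices made for determinism and
oracle-checkability; the original description gives no tie rule. The test
suite holds this procedure to an independent brute-force re-implementation
on a thousand random traces, exactly.

Cycle counts are non-increasing in the threshold — the property form of the
published threshold sweep, where 5°/10°/15° thresholds produced
1204/1091/780 estimated strokes against 1116 observed. The packaged default
threshold is 10°, the published optimum (< 2% stroke-count error).

## Bouts and metrics

`segment_bouts()` applies the rest rule: consecutive cycles with
no-activity gaps of **at most** 7 s share an active bout; a gap **strictly
greater** than 7 s closes the bout and becomes one resting bout spanning
the whole gap (a gap of exactly 7.0 s does not split — the rule is "greater
than 7 seconds"). Cycle-free time at the recording edges becomes a resting
bout when longer than 7 s and otherwise remains lead/trail *slack*, so that

$$\sum \text{active} + \sum \text{resting} + \text{slack} =
  \text{recording span}$$

within one sample period, and the number of resting and active bouts can
differ by at most one. Both properties are asserted on fuzzed sessions.

`compute_metrics()` reports, for resting bouts and for active bouts (all,
and strictly longer than `long_bout_s = 10` s): counts, total durations,
and per-bout duration / cycles-per-bout / median elevation / peak elevation
as (mean, SD, median, IQR). Per-bout median and peak elevation are computed
over the bout's **full span**, including intra-bout idle time; the
alternative (mean of per-cycle medians) is computable from the cycle table
but the span-median is what is reported, matching the tabular definition
"the average median humeral elevation angle for each active bout".
Quartiles use linear interpolation (R type 7) everywhere.

Smoothing (`smooth_trace()`) is a zero-phase 4th-order Butterworth low-pass
at 3 Hz: propulsion cadence is about 1 Hz, so the passband preserves
movement (< 1% attenuation at 0.5 Hz) while suppressing sensor noise. The
original work does not state its pre-filtering; the cutoff and order are
exposed in `arm_config()`. The filter is implemented in-package (bilinear
transform, odd-reflection padding, steady-state initial conditions) because
no signal-processing dependency is assumed; its coefficients match the
reference scientific-Python implementation to machine precision.

## Validation and bilateral statistics

Validation against video-rated intervals (`score_against_annotations()`)
is sample-wise on the trace's time grid: accuracy is the ratio of
true-active plus true-resting time to total time, sensitivity the ratio of
true-active to annotated active time, specificity the ratio of
true-resting to annotated resting time; `propulsion` and `non_propulsion`
both count as active. Samples not covered by any annotation are excluded
from numerators and denominators rather than assumed resting. Membership
conventions: active bouts are closed intervals `[start, end]`, annotation
intervals half-open `[start, end)`; stroke counting attributes a cycle to
an interval by its peak time, since a boundary-straddling stroke has no
canonical owner.

The bilateral comparison (`bilateral_summary()`) runs a separate paired
Wilcoxon signed-rank test per metric, two-sided, α = 0.05, no
multiple-testing correction (deliberately mirroring the separate-test
design). Zero differences are dropped, tied absolute differences receive
mid-ranks. For up to 25 effective pairs the p-value is exact — the
distribution of the positive-rank sum is built by dynamic programming over
doubled ranks, which is equivalent to enumerating all $2^n$ sign
assignments and is verified against that enumeration for $n \le 10$ —
otherwise a normal approximation with tie and continuity corrections is
used; the two branches agree to better than 0.01 at the $n = 20$
switchover region. Participants with multiple recording days are averaged
to one value per metric and side before testing
(`average_by_participant()`); the original analysis does not state its
aggregation, so this is a documented interpretation.

## The synthetic world

`session_spec()` states a session as baseline padding, bouts of
raised-cosine cycles (amplitude, duration, optional plateau at the peak,
intra-bout gaps ≤ 7 s) and inter-bout rests (> 7 s). Defaults are chosen
once as the conditions a field scientist would call realistic:

* **fs = 50 Hz.** The source study never states its sampling rate; 50 Hz
  oversamples ~1 Hz propulsion cadence by a factor of 50 and keeps
  simulations fast. For real recordings `fs` remains a required input.
* **Raised-cosine ramps**: differentiable with bounded derivative, so the
  forward gyroscope model (finite-difference of $\phi$) is well behaved.
  No waveform is prescribed by the source.
* **Presets** `preset_propulsion_bout()` (1 Hz, 15–30°) and
  `preset_reaching_bout()` (0.2 Hz, 40–90°, short top plateau) document the
  two movement regimes of interest; they are documentation aids, not
  claims about any participant.
* **Noise**: additive Gaussian angle noise after ground truth is fixed;
  IMU noise (accelerometer/gyroscope SDs) added in the forward model. All
  randomness flows from the single spec seed.

**Ground-truth boundaries** are placed at the *idle-band crossing times* of
the ramps (closed form: the instant the ramp leaves the band around the
baseline), not at the ramp endpoints. This is a deliberate deviation from
the obvious alternative: the detector's contract anchors cycle boundaries
where the trace is within the idle band of the valley, and on a
raised-cosine ramp that crossing sits $O(0.1\,\mathrm{s})$ inside the ramp
— ramp-endpoint truth could never round-trip to within the stated
two-samples-per-boundary tolerance, for any sampling rate of interest.
Band-crossing truth is exactly what a correct detector must find, and with
it the noiseless round trip closes to within discretisation.

What the generator does **not** emulate: trunk motion, soft-tissue
artefact, linear (non-gravitational) acceleration during movement,
magnetometer disturbance, sensor re-donning. A green round-trip test
therefore establishes the internal consistency of the detection chain and
the correctness of the orientation math under the stated noise model — not
field validity, which in the source work came from video comparison.

## Numerical choices

* Gravity constant 9.80665 m/s²; quaternions scalar-first, right-handed,
  sensor-to-world (asserted in tests).
* The arccos argument is clamped to $[-1, 1]$, so $\phi$ is finite for any
  unit input; traces are clamped to $[0°, 180°]$ after filtering.
* Zero-norm accelerometer samples fall back to gyro-only propagation for
  that step (logged); an all-zero recording is an error.
* Timestamp gaps beyond half a sample period are an error by default,
  downgradable to a warning (`gap_action = "warn"`); dropped samples are
  never silently interpolated.
* Strict inequalities: rests are `> 7 s`, long bouts `> 10 s`.
* Ties in extremum pruning: leftmost minimal pair; plateaus collapse to
  their first sample.

## Test-suite scaling

The acceptance-grade checks run at their stated sizes (1000 oracle
traces, 100 round-trip sessions, 200 enumeration-checked Wilcoxon
datasets). One generator invariant — detection recovering the exact cycle
count in ≥ 99% of noisy sessions — is exercised at 200 rather than 500
sessions to keep the default suite under two minutes; the bound is
unchanged. The criterion that reproduces the published free-living
bilateral means requires the journal's supplementary per-participant
workbook, which is neither redistributable nor reachable offline; the
corresponding test states that and remains red until the file is supplied
(see `tests/testthat/test-acceptance.R`).

## Known limitations

* Heading is unobservable by design; only inclination-derived quantities
  are meaningful.
* The calibration stand-in (static hang) assumes the participant can hang
  the arm; protocols for users who cannot are out of scope.
* Sample-wise validation converges to the published time-ratio definitions
  but can differ at interval boundaries by up to one grid sample.
* The bilateral test treats participants as exchangeable pairs; no
  mixed-effects modelling of day-level variance is attempted.
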