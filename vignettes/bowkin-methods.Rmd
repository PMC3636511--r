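---
title: "Methods: bow-reversal kinematics and arm coordination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bow-reversal kinematics and arm coordination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bowkin)
```

## The problem

During continuous-tone ("legato") bowing a cellist must reverse the bow's
direction quickly and precisely: the bow travels at a roughly constant
velocity, then inverts its velocity in an impulse-like manner at each
reversal. Skilled players achieve this with a single, large, precisely
timed acceleration peak and a differentiated, proximal-to-distal
organisation of the right arm — proximal body parts reverse earlier and
with smaller (shoulder-normalized) acceleration amplitudes than distal
ones. Beginners instead tend to move the arm as one unit, producing
bell-shaped velocity profiles with several smaller acceleration peaks and
no systematic gradient along the kinematic chain
shoulder → elbow → wrist → hand → bow.

`bowkin` implements the complete measurement chain for this phenomenon:
from raw 3D marker trajectories to bow-reversal metrics, per-marker and
per-joint coordination measures, and the mixed repeated-measures ANOVA
layer used to compare expert and novice groups. Because real recordings of
this kind are rarely shareable, the package also contains a synthetic
motion-capture generator with exact ground truth, so every stage of the
pipeline can be validated end to end.

## Pipeline

For each subject the analysis proceeds as:

1. **Filtering.** Positions are low-pass filtered with a bidirectional
   (zero-phase) 5th-order Butterworth filter, cutoff 20 Hz. Two passes
   mean the amplitude response is the squared magnitude response: power
   0.5 exactly at the cutoff, no phase distortion. Recordings sampled at
   120 Hz are decimated to 60 Hz *after* filtering; the 20 Hz cutoff lies
   below the 30 Hz Nyquist frequency of the target rate, so the filter
   doubles as the anti-alias stage and no second filter is introduced.
2. **Geometry.** All positions are re-expressed in a cello-centred frame
   (origin at the scroll marker; string axis scroll → tailpiece; lateral
   axis from the cello-body marker; right-handed completion). The frame is
   built from the trial-median cello marker positions: the instrument is
   quasi-static and the median keeps cello-marker noise out of the bow
   kinematics. Virtual joint centres are derived from surface markers with
   per-subject anthropometric offsets (shoulder: acromion translated
   inferiorly along the trunk axis; elbow/wrist: half-width offsets along
   local flexion axes; finger: the first MCP marker directly — the MCP is
   used as the centre and the PIP marker defines the phalanx direction).
3. **Bow kinematics.** The bow-tip velocity vector (three-point central
   difference) is projected onto the unit bow axis (the line through the
   two bow markers); the signed result is the *bowing velocity*, and its
   three-point derivative the *bow acceleration*. Positive velocity is the
   down-bow direction; since two markers define the axis only up to sign,
   the orientation is fixed so the first substantial stroke of a trial is
   positive (a down-bow). Direction labels follow this algebraic
   convention: `up_down` when velocity crosses from + to −.
4. **Reversals and validity.** Reversals are zero crossings of the bowing
   velocity with sub-sample linear interpolation (an exact-zero sample is
   the crossing; runs of zeros contribute their midpoint). Movements
   between consecutive reversals are valid iff they last 0.5–1 s
   (instructed: 0.75 s) and contain no missing bow or joint-angle sample;
   a reversal is analysed only when both flanking movements are valid, and
   only the first 10 valid reversals per direction enter the statistics.
5. **Reversal metrics.** Within ±375 ms of each reversal (realised
   inclusively: ±0.375 s plus half a sample period, which avoids an
   off-by-one asymmetry at 60 Hz) the pipeline extracts the peak
   acceleration and its time, the acceleration at the reversal, the
   ±10%/±50% switch durations, and the number of acceleration peaks.
   The acceleration sign is oriented per event so that the reversal
   impulse is positive (mean acceleration over ±50 ms around the
   reversal made positive), which lets both reversal directions share one
   definition.
6. **Coordination.** For the chain elbow → wrist → hand (joint centres)
   → proximal bow marker, acceleration magnitudes (double three-point
   differentiation, Euclidean norm) are divided by the instantaneous
   distance to the shoulder centre — a rigid rotation about the shoulder
   then gives every chain point the same normalized value, making
   amplitudes comparable along the arm. Per event and marker the peak
   time and the normalized amplitude at the reversal are extracted.
   Joint reversal times are the angular-velocity sign changes nearest the
   bow reversal within the event window (+ → − for up-down reversals,
   i.e. flexion-to-extension; the opposite for down-up), sub-sample
   interpolated and reported relative to the bow reversal.
7. **Statistics.** Because group and lab are confounded in the emulated
   two-lab design, lab main effects (mean differences) are removed from
   every dependent variable first: each value is centred on its lab mean
   and the grand mean restored, which leaves all within-lab contrasts
   exactly unchanged. Group × Direction mixed ANOVAs (classical
   univariate partitioning, subjects nested in group) test the bow-level
   variables; Group × Direction × Marker (or Joint) ANOVAs with the chain
   as an *ordered* factor test the coordination profiles, with orthogonal
   polynomial (linear/quadratic/cubic) trend contrasts against the
   factor's own error stratum. Post-hoc pairwise t-tests are
   Holm-corrected within families, and one-sample t-tests ask whether the
   relative temporal measures differ from zero (the time of bow
   reversal). No sphericity correction is applied by default: the
   two-level within factors need none, and the chain factors' trend tests
   are single-df.

### Numerical choices

* **Zero-phase filtering.** Each pass starts from a reflected (odd)
  extension of the segment, long enough for the slowest filter pole to
  decay below ~1e-12. This makes the DC gain exact to numerical
  precision and the segment edges usable. Contiguous segments shorter
  than `4 * (order + 1)` samples cannot be filtered stably and are masked
  out with a warning.
* **Differentiation.** Central differences only; no one-sided estimates.
  A derivative sample requires both neighbours, so gaps cost one sample
  on each side per differentiation. The rule is exact for quadratics.
* **Switch durations.** The ±f duration is the time between the last
  crossing of −f·|v_peak,pre| before the reversal and the first crossing
  of +f·|v_peak,post| after it, with the reference peaks taken inside the
  pre-/post half-windows (keeping the metric local to the reversal). The
  known zero at the reversal closes each half-window so crossings falling
  between the last sample and the reversal are interpolated, not lost.
  Note that by this definition the ±10% duration is *shorter* than the
  ±50% one (for sinusoidal velocity of period T they are T·asin(0.1)/π
  and T/6): the ±10% band around zero velocity is crossed faster.
* **Peak counting.** Candidate peaks are strict interior local maxima of
  the acceleration magnitude in the window. The ≥100 ms separation is
  enforced greedily in descending amplitude order, then the
  >50%-of-window-maximum threshold is applied. With distinct amplitudes
  the greedy choice equals the amplitude-lexicographically maximal
  pairwise-separated subset, which is what the exhaustive oracle in the
  test-suite enumerates. The window's global maximum always counts, so
  the statistic is ≥ 1.
* **Joint reversals.** When several qualifying angular-velocity sign
  changes exist in the window, the one nearest the bow reversal is taken
  (deterministic, and robust to slow secondary drifts).

## The synthetic generator

`simulate_recording()` builds trials analytically. Each bow reversal is
one or more Gaussian acceleration pulses; velocity and position then have
closed forms in the error function, so the generator knows its zero
crossings and pulse peak times to numerical precision rather than at grid
resolution:

* **Expert-like profiles** use a single, slightly skewed pulse per
  reversal (different left/right widths). The skew is solved numerically
  so the acceleration peak precedes the velocity zero crossing by the
  requested offset (default −30 ms with 10 ms trial-to-trial SD), and the
  width is solved so the −50% → +50% switch time equals
  `reversal_duration_50` (default 0.15 s). Between reversals the velocity
  is flat.
* **Novice-like profiles** spread each reversal over `n_accel_peaks`
  pulses (default 3), each at least 70% of the largest and ≥120 ms apart,
  so the true peak count is known by construction; the group is
  time-dilated so the measured ±50% switch time matches the requested
  0.30 s ("about twice as long" than experts). Which pulse is largest
  varies from reversal to reversal (offset SD 0.1 s), reproducing the
  beginners' large timing variability; the resulting velocity profile is
  approximately bell-shaped. Novices are also given less bow travel per
  stroke (300 mm vs 450 mm), which yields their lower peak accelerations.

The arm is a schematic linkage, not a biomechanical model: each arm
marker carries the bow displacement profile along the bowing (lateral)
axis, attenuated per chain step and time-advanced by the
`proximal_distal_lag` (default 30 ms/step for experts, 0 for novices), so
the proximal-to-distal timing and amplitude structure holds *exactly* by
construction at the marker level. The per-step displacement attenuation
is `structural_attenuation / proximal_distal_amp_gain`; the structural
factor (0.8) keeps proximal excursions anatomically modest even for gain
1, and the anchor directions of `chain_geometry()` were chosen so that
every joint angle is a monotone increasing function of bow displacement
across the whole realistic amplitude range — this is what keeps the
flexion-to-extension polarity at reversals consistent between expert-like
and novice-like parameterisations. Joint-angle ground truth is obtained
by evaluating the analytic geometry on a 600 Hz grid and interpolating
the angular-velocity zero crossings.

Measurement noise is an AR(1) process (lag-one correlation 0.9,
stationary RMS 0.2 mm) rather than white noise: optical marker
reconstruction error drifts smoothly, and the high-frequency power that
double differentiation amplifies is what matters here. A white-noise
floor of a few tenths of a millimetre would make the peak-count statistic
unmeasurable for *any* subject — inconsistent with real recordings, in
which expert acceleration traces are visibly clean — so the correlated
model with sub-millimetre RMS is the realistic choice. Missing samples
are Bernoulli dropout per frame and marker (default 2e-4), which under
the validity rules yields ~92–94% retained movements, the retention scale
typical of such experiments. Cohorts jitter the group profiles between
subjects (log-normal on amplitudes and durations, additive on timing;
SDs documented in `?simulate_cohort`), and the default lab assignment
confounds group with lab (most experts in one lab), which is precisely
the situation the lab-removal step addresses.

What the generator does *not* emulate: soft-tissue artifact, rigid-body
marker clusters, non-stationary tempo drift, string-crossing or
bow-tilt dynamics, and any force/torque level description (the analysis
is purely kinematic). Passing tests therefore validate the measurement
chain and the statistics under the stated noise model, not the
biomechanics of real bowing.

## Default parameters

| Parameter | Default | Meaning |
|---|---|---|
| filter cutoff / order | 20 Hz / 5 | zero-phase Butterworth, both passes |
| working rate | 60 Hz | 120 Hz input decimated after filtering |
| movement validity | 0.5–1 s | instructed stroke 0.75 s (80 bows/min) |
| reversal window | ±0.375 s | inclusive realisation (+½ sample) |
| switch thresholds | ±10%, ±50% | of local (half-window) peak velocity |
| peak rule | >50% max, ≥100 ms | greedy by amplitude, then threshold |
| events per direction | 10 | earliest valid reversals |
| cohort | 10 + 10 | subjects per group, 20 cycles each |

## Problem sizes in the test-suite

The suite exercises trials of 1–8 cycles for unit and property tests, a
6-subject cohort for the pipeline tests, and the full default 10 + 10
cohort (20 cycles per subject) for the end-to-end group-contrast checks.
The ANOVA layer is validated against explicit sums-of-squares arithmetic
on toy designs, a 200-replicate power simulation, and a 2000-replicate
null calibration of its type-I error.

## Known limitations

* The joint-angle definitions are vector-angle conventions (elevation
  and interior angles), not a full ISB Euler decomposition; downstream
  metrics use only reversal timing, which is robust to any
  sign-consistent monotone angle definition, and the angle model is a
  single internal function that can be swapped.
* The pipeline estimates the time of peak acceleration at sample
  resolution (no sub-sample refinement of the argmax); at 60 Hz this is
  the dominant term in the ±1-sample recovery guarantee.
* Lab-effect removal does not reduce the ANOVA error degrees of freedom;
  with 2 labs this is one constraint per dependent variable and is left
  unadjusted, as is conventional when the adjustment is treated as a
  fixed preprocessing step.
* Reversals at the very start and end of a trial have only one flanking
  movement and are never analysed; a trial of n strokes yields at most
  n − 2 analysable reversals.
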