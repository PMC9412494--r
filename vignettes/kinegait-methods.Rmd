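---
title: "kinegait: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{kinegait: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinegait)
```

`kinegait` turns time-stamped 3D skeletal joint trajectories of a subject
walking toward a depth camera into quantitative gait descriptors, with an
emphasis on arm swing, its left/right asymmetry, and limb synchrony. This
vignette explains the processing model, the parameters that matter, the
numerical choices behind each stage, and what the synthetic-data validation
does and does not establish.

## Coordinate and data model

A trial is a `skeleton_sequence`: strictly increasing timestamps (seconds)
and, per frame, 3D positions (millimetres, camera frame) of 32 body-tracking
joints. Conventions: `x` mediolateral (positive toward the subject's left),
`y` vertical (positive up), `z` distance from the camera — the subject walks
toward the sensor, so pelvis `z` decreases. The motion components are named
AP (anteroposterior, from `z`), ML (mediolateral, `x`) and UD (up–down,
`y`). Per-joint confidence scores are stored and round-tripped but never
gate the analysis; tracking-quality filtering is a deliberate non-goal at
this stage.

Trial files are one JSON object per trial
(`frames: [{t, joints: {NAME: {p: [x, y, z], c}}}]`, `schema_version: 1`).
This schema is the package's own emulation of the per-joint JSON exports
that depth-camera acquisition front ends produce; it is not a vendor format.
Serialization uses 17 significant digits so write/read is bit-exact.

## Preprocessing

**Resampling.** Consumer depth sensors deliver ~30 fps with jittered
timestamps. Every joint coordinate is independently interpolated onto a
uniform 50 Hz grid spanning the raw trial. Up-sampling (rather than
decimating to a common lower rate) densifies the trajectories without
discarding frames. The interpolant is a cubic spline with
Forsythe–Malcolm–Moler end conditions (`stats::splinefun(method = "fmm")`),
chosen because it invents no boundary slopes and reproduces any single cubic
polynomial exactly — the property the resampling tests pin down to 1e-6 mm.

**Filtering.** A 4th-order Butterworth low-pass at 8 Hz, applied forward
and backward per coordinate so there is no phase lag — temporal event
estimates would otherwise be biased by the filter's group delay. 8 Hz
retains voluntary gait movement in healthy and impaired adults while
suppressing tracking noise; order 4 is the biomechanics convention. Because
the forward–backward pass squares the magnitude response, the tests check
the measured gains against the closed-form squared Butterworth response
(within 1% of unity at 2 Hz; below 0.05 at 15 Hz). One numerical caveat:
zero-phase filtering is only as good as its end handling, so the filter is
applied to an odd-reflection extension of each series (100 samples per end)
and trimmed back, letting the start-up transient decay outside the data.
Filtering precedes windowing for the same reason: any residual edge effect
falls outside the analysis corridor.

**The gait analysis path (GAP).** All metrics are computed on the samples
where the pelvis lies between configurable near/far distances from the
camera (defaults 1.5 m and 3.5 m — a 2 m corridor inside the depth sensor's
reliable tracking range; the bounds are configuration, not inference).
Entry and exit times are linear interpolations of the pelvis-`z` boundary
crossings; gait velocity is corridor length over traversal time. A trial
that ends inside the corridor yields a truncated window with a warning
rather than an error, since the remaining samples are still analyzable.

## Gait events and spatiotemporal parameters

Event detection uses the ankle's anteroposterior position **relative to the
pelvis**, `f(t) = pelvis_z − ankle_z`: subtracting the pelvis removes the
forward drift of overground walking, leaving a bounded oscillation whose
maxima are heel strikes (foot maximally ahead of the body) and whose minima
are toe-offs. Peaks must reach 10 mm topographic prominence and be at least
0.3 s apart (both configurable); prominence — rather than raw height —
makes the rule insensitive to slow residual trends. The peak finder is
oracle-tested against an exhaustive local-extremum scan. Left and right
heel strikes must alternate; violations produce a warning naming the
offending times rather than silent acceptance.

Per-side parameters average over that side's events inside the window: step
length is the ankle separation in `z` at heel strike, step time the
interval from the contralateral strike, stance duration the own-strike to
own-toe-off fraction of the stride, double support the interval from a
strike to the other side's next toe-off. Cadence is defined from the window
itself — 60 × completed steps / traversal time — rather than from inverted
step time; on a 2 m corridor holding only a handful of steps the two
definitions disagree, and the window-count definition is the one that stays
consistent with the reported step counts. A side with fewer than two heel
strikes gets `NA` stride metrics and a warning instead of fabricated
values.

## Center-of-mass sway

The COM proxy is the hip midpoint. Sway is the **maximum absolute
deviation from the straight walking line**, computed separately for the
lateral and vertical coordinates against the forward coordinate `z` (not
time), so walking at a constant angle to the camera axis is absorbed by the
reference line — an invariance the tests assert to 1 mm.

Estimating that reference line on a 2 m window is the one genuinely
delicate numerical choice in the package. The corridor holds only one to
three periods of the periodic COM oscillation, and an ordinary
least-squares line fitted through so few periods tilts toward the phase of
the oscillation, over-reading a pure sinusoidal sway by 8–16% — while
simultaneously under-reading a single one-sided excursion, because the
excursion drags the line toward itself. The package therefore fits the line
jointly with a first-harmonic regressor at the dominant oscillation
frequency (selected by a coarse-to-fine least-squares scan over 0.3–3 Hz,
the stride-to-step band of adult gait) under a robust bisquare loss
(`MASS::rlm`), and then measures the deviation from the **line component
only**. The harmonic term keeps the periodic sway out of the line; the
robust loss keeps isolated excursions out of it; both then register in full
in the deviation. Validated behaviors: sinusoidal amplitudes recovered
within ~1% at zero noise across phases and periods; a single 40 mm
excursion on an otherwise straight path measured as 40 mm; translation and
linear-drift invariance. Vertical sway is treated identically; note that it
measures deviation from the linear trend only and retains gait's intrinsic
double-bump vertical motion as signal, not trend.

## Arm swing

Linear measures use the wrist displacement relative to the pelvis:
AP = `pelvis_z − wrist_z` (positive anterior), ML = `wrist_x − pelvis_x`,
UD = `wrist_y − pelvis_y`. Per direction the anterior maximum, posterior
minimum and peak-to-peak range are reported (the range identities
`RANGE = ANT − POS` hold by construction and are asserted on every trial);
additionally the total 3D path of the relative wrist motion, the convex-hull
area of the (AP, ML) point cloud (shoelace formula on `grDevices::chull`;
degenerate point sets yield area 0 with a warning), and the peak AP speed
by central differences on the 50 Hz grid.

Angular measures project the arm vector (wrist − shoulder) and the
same-side trunk vector (hip − shoulder) onto the sagittal plane and take
the signed planar angle, positive when the arm is anterior of the trunk
line. A signed planar angle — rather than an unsigned 3D angle — is what
makes the anterior/posterior decomposition meaningful. Samples with
projected vectors shorter than 10 mm are excluded (warning above 5%
exclusions).

**Asymmetry.** The absolute symmetry angle of a positive left/right pair
(`P_MORE` the larger, `P_LESS` the smaller) is

$$\mathrm{ASA} = \left|\frac{45^\circ - \arctan(P_\mathrm{MORE}/P_\mathrm{LESS})}{90^\circ}\right| \times 100\,\%$$

with `asa(x, x) = 0`, a supremum of 50 reached exactly at `P_LESS = 0`,
symmetry in its arguments and scale invariance — all asserted
property-style. The three reported indices apply it to the angular range
(`ASA_ANGLE`), the wrist path (`ASA_PATH`) and the AP sway range
(`ASA_AP_RANGE`). `ASA_ANGLE` is deliberately computed from the angular
*range* rather than the anterior maximum: the two conventions circulate,
but only the range-based one is numerically consistent with the published
worked examples this package reproduces, so the range is the documented
choice here.

**Synchrony.** Pearson correlations of anteroposterior signals:
`SI_ARMS` between the two wrist-relative AP series (healthy arms swing in
opposition, so values near −1 indicate strong coordination), and
`SI_ARM_LEG` between the `z`-extent of an arm segment (wrist − shoulder)
and of the opposite leg segment (ankle − hip), signed so that coordinated
opposite-limb motion is positive. The segment-difference reading (rather
than distal-joint displacement) is the adopted interpretation of
"arm segment versus opposite leg segment"; it is documented rather than
load-bearing, since both readings correlate near unity on coordinated gait.

## The synthetic walking simulator

`synth_config()`/`generate_trial()` produce trials with closed-form ground
truth, which is what makes the pipeline testable without recorded data.
The model: the pelvis advances at constant speed (step length / step time)
with sinusoidal lateral COM motion at the stride frequency and vertical
motion at the step frequency; ankles alternate stance (AP position frozen)
and swing phases at the configured stance fraction; wrists swing as
sagittal pendulums of configured per-side angular amplitude, anti-phase
between arms and in phase with the contralateral leg; the remaining joints
ride rigidly on the pelvis or their parent segment. Timestamps are drawn at
a jittered ~30 fps and isotropic Gaussian noise (default sd 2 mm) is added
last, after all kinematics, so the ground truth stays closed-form. A seed
fixes the full output bit-exactly, and the caller's RNG state is preserved.

Two shape choices deserve a note. The swing-phase ankle transport is a
blend of linear and cosine-ramp motion (blend 0.6): the blend keeps the
foot's lift-off/landing speed above the pelvis speed, which makes the
extrema of the pelvis-relative ankle trace coincide with the true contact
times — a pure cosine ramp, with zero endpoint velocity, would shift those
extrema ~30 ms into swing and bias stance-duration recovery by several
percentage points without representing anything physiological. Second, foot
strikes land half a step length ahead of the pelvis, which makes step
length, stride length and step time exact functions of the configuration.

Default configuration (step 0.60 m / 0.55 s, stance fraction 0.62, arm
amplitude 25° per side, COM sway 55/40 mm, 30 fps with 3 ms jitter, 2 mm
noise) represents a comfortable healthy adult walk; the values sit inside
the healthy-control ranges reported for walkway studies of this design.
Parameter-recovery tests run at these conditions and assert recovery of
step length/time, gait velocity, angular range, AP sway range and lateral
sway within 5%, ASA indices within 1.5 percentage points, and
`SI_ARMS ≤ −0.9` for the anti-phase construction.

What the simulator does **not** emulate — and therefore what passing tests
do not establish about real data: body-tracking outliers and dropouts,
joint-confidence dynamics, turning or hesitation, tremor or freezing
episodes, soft-tissue and clothing artifacts, and inter-stride variability
(each simulated stride is identical up to noise). Results on recorded
trials additionally depend on the acquisition system's tracking quality.

## Statistical reporting

`compare_groups()` mirrors the conventions of small-cohort gait studies:
per parameter, group medians with first/third quartiles, the Mann–Whitney
test (reported as the rank sum of the first group,
`W = U + n_1(n_1+1)/2`; exact p for small untied samples, tie-corrected
normal approximation otherwise, as implemented by `stats::wilcox.test`),
Student's t as a parametric companion, Shapiro–Wilk normality p per group,
and significance stars at 0.05/0.01/0.001. Parameters estimated per side
contribute the left and right values as separate observations — doubling
the sample for side-wise parameters, as is common in this literature — with
the documented caveat that this ignores within-subject correlation between
sides. No multiple-testing correction is applied; p-values are reported
per parameter, raw. `correlation_matrix()` crosses arm-swing parameters
with spatiotemporal and COM parameters using Spearman's rank correlation
(primary) and Pearson's (companion), each cell carrying its significance
tier; constant columns yield cells marked undefined rather than errors.

## Problem sizes and determinism

The test suite and validation scripts run entirely on simulated data:
single trials of ~4 s (~125 frames raw, ~200 samples at 50 Hz) and cohorts
of up to 58 trials (16 + 13 subjects × 2 trials, matching the two-group
design the reporting layer is meant for). A full 58-trial
generate–write–read–analyze–compare cycle completes in under two minutes on
one CPU. Every random quantity — simulator noise, jitter, test fixtures —
is seed-controlled; `analyze_trial()` itself is deterministic, and
re-running it on the same file reproduces the row exactly.

## Known limitations

* Event detection assumes walking **toward** the camera along the corridor;
  away-from-camera or oblique protocols would need sign and reference
  changes.
* On a 2 m corridor a side frequently contributes only one or two strides;
  stride-level parameters are then missing or high-variance by nature, and
  cadence from window counts is coarse (quantized by the step count).
* The ASA is undefined when both sides are zero and saturates at 50% when
  one side vanishes; near-zero denominators make it sensitive to
  measurement noise in severely reduced swing.
* Confidence scores are carried but unused; heavily occluded recordings
  will degrade results without warning flags tied to tracking quality.
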