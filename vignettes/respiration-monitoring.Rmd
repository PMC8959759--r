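---
title: "Contactless respiration monitoring: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contactless respiration monitoring: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(respiradar)
```

## The monitoring problem

respiradar implements a pipeline for monitoring the breathing of up to two
people in a room without body contact. Two sensor modalities cooperate:

* **IR-UWB radars** emit short pulses and resolve echoes into *range bins*
  of about 5.22 cm. Stacking successive pulses gives a *slow-time ×
  fast-time* matrix: each column is the echo amplitude at one distance over
  time. A breathing chest a distance $d$ from the radar modulates the
  amplitude of bin $\mathrm{round}(d / 0.0522)$ at the respiration rate.
  With a 9.4 m recording range the matrix has 180 columns; the slow-time
  rate is 17 Hz.
* **A depth camera** tracks three skeleton joints per subject — chest, left
  shoulder, right shoulder — at about 1 frame/s. The camera is pole-mounted
  and tilted about its x axis by an angle $A$ (default $-30°$), so joints
  arrive in a rotated frame and are corrected by
  $p_0 = R_x(A)\,p_{rot}$ (`rotate_to_reference()`).

The camera answers *where* each subject is and *whether they are moving*;
the radars provide the respiratory waveform. Every 15-s analysis window the
pipeline decides, per subject: moving or stationary (average shoulder-
midpoint speed against 0.7 m/s, about slow walking); which radar to read;
which range bin carries the chest; which of five respiration patterns the
chunk shows — eupnea, Cheyne-Stokes respiration (CSR), Kussmaul, apnea,
non-stationary — and, only for quality-passing eupnea, the respiration rate
$RR = 60/\overline{\Delta t}$ from the mean peak-to-peak interval.

## Radar selection geometry

A subject is inside a radar's detection area when the chest lies within the
60° beam (half-angle 30° around the boresight, measured in the horizontal
xz plane) and closer than 5 m. Among covering radars, the one whose
*orientation angle* is closest to 90° wins. The orientation angle
$\angle RMD$ sits at the shoulder midpoint $M$ between the right shoulder
$R$ and the radar $D$ (all projected to the xz plane):

$$\angle RMD = \arccos\frac{RM^2 + MD^2 - RD^2}{2\,RM\,MD}$$

A subject squarely facing the radar gives exactly 90°.

With two subjects there is a physical constraint: if both chests lie within
6 range bins (≈ 30 cm) of the same distance inside one radar's beam, their
echoes occupy the same narrow band of bins and neither signal can be
isolated there. `assign_radars()` therefore treats such a radar as unusable
for the affected subject — *whoever it is oriented toward* — and falls back
to the covering radar with the next-best orientation angle
(`fallback_separation`), or reports the subject `uncovered` when no usable
radar remains. We deliberately resolve the conflict by physical presence
rather than by letting the better-oriented subject "keep" the contested
radar: the corrupted bins contain both echoes, so no keeper could use them
either. Ties on $|\angle RMD - 90°|$ break toward the lower radar id, and
because usability depends only on geometry the assignment is independent of
subject ordering.

## Preprocessing

All streams are resampled to 17 Hz (linear interpolation — the respiration
band lives far below Nyquist). Clutter is removed in two steps:

* `svd_clutter_removal()` subtracts the top singular component(s) of the
  matrix. Static clutter is constant over slow time — exactly rank one —
  and dominates the leading component of a raw recording; one component is
  the default.
* `remove_background()` subtracts a per-bin amplitude profile, by default
  the per-bin mean over a 5-s calibration prefix.

**Order matters.** The combined helper `preprocess_radar_matrix()` runs the
SVD *first*, on the raw matrix, and subtracts the background afterwards.
If a background estimated from the matrix itself is subtracted first, the
static clutter is already gone and the breathing modulation becomes the
leading singular direction — truncating it would erase the signal (we
measured the breathing-bin variance collapsing by three orders of magnitude
in that order). With a separately recorded empty-room background vector the
conventional order is fine: subtract it explicitly, then call the SVD.

## Signal extraction and rate estimation

Candidate bins are $\mathrm{round}(d/0.0522) \pm 3$ (± the thickness of a
torso); the candidate with maximal slow-time variance is the respiratory
signal. Rate estimation bandpasses the chunk with a zero-phase 3rd-order
Butterworth filter, 0.1–0.5 Hz (6–30 breaths/min) — forward-backward so
peak times are not shifted, with the mean removed first since filtfilt edge
transients scale with the DC offset — then averages peak-to-peak intervals.
Fewer than two peaks yields an explicit no-estimate.

## Pattern classification and the discriminator

A random forest (100 trees, other hyperparameters at library defaults,
seeded) classifies 13 statistical features per 15-s chunk:

* time domain: SD / mean / max of detected peak amplitudes, peak count;
* time-frequency: SD / mean / max / min / range of the instantaneous
  frequency, computed from the FFT-based analytic signal as the derivative
  of the unwrapped phase over $2\pi$, trimming 0.5 s at each end against
  edge artifacts;
* short-term energy: SD / max / min / range of the energy over three
  non-overlapping 5-s segments.

"Variability" is the sample standard deviation throughout. Degenerate
chunks take a defined path: no peaks → zero peak statistics; constant chunk
→ zero IF statistics as well (energies are still computed).

The **signal quality index** then gates the label morphologically: median
filter (kernel 5), min–max normalization to [0, 1], peaks and troughs with
topographic prominence strictly greater than 0.15, valid breaths =
consecutive peak pairs enclosing a trough. A chunk passes when it has at
least 3 valid breath intervals and their normalized SD (SD/mean) is
strictly below 0.25. Note the arithmetic consequence: a 15-s chunk needs 4
detectable peaks for 3 intervals, so breathing below ~14 breaths/min cannot
pass — the gate defines "good-quality" eupnea as the faster part of the
resting range.

The final label follows the override rules: an apnea label bypasses the
quality gate (an apnea chunk has no breaths and could never satisfy it —
gating it would make the class undetectable); any other label failing the
SQI becomes non-stationary; a CSR label is confirmed only when peak
amplitudes strictly increase to the maximum-amplitude peak and strictly
decrease after it (the crescendo–decrescendo tidal-volume envelope),
otherwise it is demoted to eupnea. The strictness makes confirmation
noise-sensitive — two near-equal central peaks demote a genuine CSR chunk —
which is consistent with the moderate CSR recall such systems report.
`discriminate()` is idempotent. The respiration rate is emitted only for
stationary subjects whose final label is eupnea and whose chunk passed the
SQI; this gate is asserted on every processed window.

## The simulator: what it emulates, and what it does not

`gen_respiratory_waveform()` produces chest displacement per pattern:
eupnea and Kussmaul are quasi-sinusoids with mild smooth frequency (3%) and
amplitude (5%) jitter and a random initial phase (chunks are cut from
ongoing streams); apnea gates a contiguous fraction of the window to zero;
CSR is a carrier under a raised-cosine crescendo–decrescendo envelope with
a silent tail covering `apnea_fraction` of each `csr_period_s` (> 15 s, as
CSR cycles are); non-stationary is a random walk with occasional steps.

`gen_radar_matrix()` uses a deliberately minimal additive echo model:
per-bin static clutter (sd `10·clutter_sd`) plus white noise (sd
`clutter_sd`), with the subject's waveform added at the chest bin with
triangular spillover to the two adjacent bins, scaled by an orientation
gain — the cosine of the angle between facing direction and subject→radar
direction, clipped at zero, and zero outside the detection area. This is
the smallest model that reproduces the property the extractor relies on
(maximum slow-time variance at the chest bin) and the radar-selection
behavior (signal quality degrading as the subject turns away). It does
*not* model electromagnetic propagation, antenna patterns beyond the cosine
gain, multipath, range-dependent attenuation, harmonics of chest motion, or
complex/IQ processing — passing tests show the *pipeline logic* is correct
under the stated statistical structure, not that the system would meet the
same numbers on hardware recordings.

The training database (`gen_training_database()`, 50 chunks/class → 250 by
default) draws per-chunk parameters from class-typical ranges chosen as the
study conditions: eupnea 14–22 breaths/min (the monitored-adult resting
range the 15-s quality criteria are designed around), Kussmaul 25–38 at
2–3× amplitude, apnea windows 70–100% flat, CSR cycles of 30–60 s with a
16–24 bpm carrier — CSR chunks are cut from the crescendo/decrescendo
portion of the cycle, where the pattern's morphology lives (a gap-only cut
is indistinguishable from apnea) — and non-stationary random walks.

## Numerical choices

* Range bins are indexed from 0, so bin $b$ is matrix column $b+1$ and
  $\mathrm{round}(d/0.0522)$ is directly the bin index.
* Prominence is topographic (height above the higher of the two key
  saddles), computed exactly; thresholds (prominence 0.15, NSD 0.25) are
  strict inequalities, and the boundary cases are pinned in tests.
* The median filter uses `stats::runmed` with median end-rule; plateaus
  produced by filtering count as a single peak at their left edge.
* Rotations are exact orthogonal matrices (round-trip error < 1e-12);
  `acos` arguments are clamped to [−1, 1] against rounding.
* Degenerate inputs have defined outcomes: single skeleton sample →
  stationary (logged); > 50% dropped skeleton frames → treated as moving
  (fail-safe, no rate emitted); flat chunk → zero breaths, SQI fail;
  subject beyond the recorded range → contributes nothing (logged).
* Determinism: every stochastic operation takes a seed and restores the
  caller's RNG state; identical seeds give bit-identical outputs.

## Problem sizes in the test suite

The suite exercises the pipeline at sizes chosen to characterize behavior
compactly: rate recovery over {8, 12, 15, 20, 25} breaths/min × 20 seeds of
single-subject 15-s scenes (median absolute error ≤ 0.5 bpm); bin-selection
accuracy over a clutter grid of {0.1, 1, 3} × 30 seeds (monotone
non-increasing); the classifier over the 250-chunk database with 10-fold
cross-validation plus a 150-chunk held-out set; and a 60-s two-subject
recording through the file-based pipeline (16 windows at stride 3 s).

## Known limitations

* The two-subject conflict resolution reconstructs behavior from a worked
  example; the original selection pseudocode is not public.
* Skeleton association is by stable subject id; re-identification after
  occlusion is out of scope, as are posture analysis and fall detection.
* Batch processing over files replaces the real-time transport; the
  windowing semantics (15 s window, 12 s overlap, 3 s stride) are
  identical.
* The orientation angle is symmetric about 90° (a subject facing exactly
  away also scores near 90°); the cosine gain in the simulator breaks the
  tie physically, but the selector cannot distinguish the two poses from
  geometry alone.
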