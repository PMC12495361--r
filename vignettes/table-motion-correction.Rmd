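---
title: "Table-motion-corrected respiratory surrogate signals: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Table-motion-corrected respiratory surrogate signals: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathtrace)
```

## The problem

External respiratory surrogate systems track a marker on the patient's chest
to gate CT acquisition (4DCT) or to coach breath-holds (DIBH). A ceiling- or
table-mounted camera, however, cannot distinguish true anterior-posterior
(AP) breathing motion from motion of the CT couch itself: couch feed between
axial acquisitions and couch *sag* under patient load both contaminate the
measured signal. Deflections of a few millimetres are enough to misassign
amplitude bins in 4DCT or to mislead a visually coached patient.

`breathtrace` implements a dual-marker correction: a second, rigid reference
marker is mounted on the couch at the same longitudinal position as the
patient marker, so that any couch motion appears identically in both
streams and can be removed by subtraction.

## Coordinate model

The tracker reports each marker as a time-stamped 4x4 homogeneous transform
in the camera's global frame. Because the camera views the couch at a pitch
angle $\theta$ (rotation about the lateral $y$ axis), global coordinates are
rotated into the patient frame by

$$
\begin{pmatrix} x_{AP} \\ y_{ML} \\ z_{CC} \end{pmatrix} =
\begin{pmatrix}
\cos\theta & 0 & \sin\theta \\ 0 & 1 & 0 \\ -\sin\theta & 0 & \cos\theta
\end{pmatrix}
\begin{pmatrix} x_g \\ y_g \\ z_g \end{pmatrix}.
$$

The pitch is read from the marker orientation matrix as
$\theta = \arcsin(-R_{31})$ (principal branch). The AP projections of the
two markers,

$$
x_\text{breathing} = x_{g,p}\cos\theta + z_{g,p}\sin\theta, \qquad
x_\text{table} = x_{g,t}\cos\theta + z_{g,t}\sin\theta,
$$

are subtracted sample-wise to give the corrected breathing signal
$x_\text{corrected} = x_\text{breathing} - x_\text{table}$ — exact
subtraction, never smoothed or rescaled. Anterior displacement is positive;
couch sag is therefore negative.

Conventions fixed by the package (the source instrumentation leaves them
open):

* **One $\theta$ per session.** `estimate_pitch()` takes the median of
  per-frame pitch extractions over the first second of the *table* marker
  stream. The camera angle is a property of the room, and a per-frame
  $\theta$ would leak marker-orientation noise into the position correction.
  The table marker is preferred over the patient marker because it is rigid
  and stationary during the calibration window.
* **Rejection, not repair.** Rotation blocks must be orthonormal with
  determinant $+1$ to within $10^{-6}$; anything worse raises an
  `invalid_rotation` error.
* **Stream pairing.** The two marker streams may be asynchronous (the
  simulator models a constant 16.6 ms latency on the table stream). The
  table signal is linearly interpolated onto the patient timestamps —
  couch motion is slow and piecewise smooth, so linear interpolation is
  adequate — and patient samples whose nearest table frame is farther than
  `max_gap` (default 0.2 s, a few frames at typical tracker rates) are
  dropped rather than extrapolated.

## Signal-quality metrics

* **DIBH reproducibility**: mean and sample SD of the mean amplitude across
  successive breath-hold plateaus.
* **DIBH stability**: intra-breath-hold drift, the ordinary least-squares
  slope (mm/s) of amplitude over the plateau interior.
* **4DCT amplitude/duration stability**: per-cycle peak-to-trough amplitude
  and max-to-max cycle duration, summarised as mean and sample SD.
* **Baseline shift**: amplitude at the last end-expiration minimum minus
  amplitude at the first one; negative values indicate a sagging baseline.
  This is the headline 4DCT quality figure, since uncorrected couch sag
  shows up directly here.

All SDs use the sample ($n-1$) convention. Cohort tables aggregate
per-subject (mean, SD) pairs two ways: mean ± SD of the per-subject means,
and mean ± SD of the per-subject SDs. Aggregates are computed at full
precision; `round_report()` applies one-decimal presentation rounding
half-away-from-zero with a floating-point guard (a cohort mean of exactly
10.95 must print as 11.0, which naive double rounding misses).

### Plateau detection

The breath-hold literature defines plateau metrics but not a segmentation
algorithm, so the package fixes one:

1. smooth the trace with a centred moving average (default **0.25 s**);
2. mark samples where the smoothed derivative magnitude is at most
   `slope_tol` (default **1 mm/s**) *and* the level exceeds 50% of the
   trace's 95th-percentile amplitude (this adaptive height gate excludes
   free-breathing peaks, which can be momentarily flat);
3. merge runs and keep those at least `min_duration` long (default **5 s**,
   the hold length patients are coached to sustain);
4. refine each run boundary outward using *raw* first differences against
   the same slope tolerance. On clean signals this recovers the flat-top
   corners to within one sample — the smoothing in step 1 alone would bite
   roughly half a window off each edge. Under realistic tracking noise the
   raw differences exceed the tolerance immediately, so the refinement is a
   no-op there;
5. trim 10% of samples from each end of the plateau before computing its
   mean amplitude and drift, so inhale/exhale ramps cannot bias either.

### Minima, maxima and cycles

Cycle maxima and end-expiration minima are local extrema passing a
topographic-prominence gate (default **20% of the signal range**) with a
minimum separation (default **0.5 s**). Prominence makes the detection
robust to the ~0.06 mm RMS tracking noise, which produces countless
micro-extrema of negligible prominence. For the baseline shift the minima
*amplitudes* are read from the lightly smoothed trace (same 0.25 s window):
a single-sample read would carry the full noise amplitude into a metric
whose interesting scale is a quarter millimetre, while the smoothing
attenuation is identical at both minima of a quasi-periodic signal and so
cancels in the difference.

### Scenario comparison

`compare_scenarios()` follows the study's decision rule: Shapiro-Wilk
normality on both groups; when both are compatible with normality
(p > 0.05) a paired t-test, otherwise a Mann-Whitney U test. An unpaired
t-test variant is available via `paired = FALSE` but is not the default.
Exactly constant paired differences leave the t-test undefined and raise a
`degenerate_test` error rather than returning a spurious p-value.

## Visual feedback

The patient-facing display is driven by a breathing window:

* **Static DIBH window**: a fixed corridor (default width 5 mm, draggable
  by configuration).
* **Dynamic 4DCT window**: a corridor of constant half-width (default
  2.5 mm) centred on the guidance waveform

  $$ g(t) = A\left(1 - \cos^{6}\!\frac{\pi t}{T}\right), $$

  with study parameters $A = 30$ mm and $T = 10$ s. The orientation is
  chosen so $g(0)=0$ is the end-exhale resting baseline and $A$ is the
  peak-to-trough span; the even cosine power produces the long exhale dwell
  and brisk inhale characteristic of natural breathing. Window bounds may
  go negative near end-exhale; clipping is a display concern.

Each sample is classified `within` / `edge` / `outside` (green / yellow /
red). The yellow zone width defaults to 10% of the window width — the
source display shows but does not quantify it — and must stay below half
the width. Classification is monotone: moving toward the window centre
never demotes the state.

## The simulator

`simulate_session()` is the test bed standing in for camera, couch and
scanner. It emulates:

* **Breathing patterns**: sinusoid $(A/2)(1-\cos 2\pi f t)$ (phantom 4DCT
  protocol: 0.2 Hz, 20 mm), the cos^6 guidance waveform, and a DIBH
  sequence of `n_plateaus` flat holds (phantom protocol: three 6.5 s holds
  at 20 mm) entered through 1 s linear ramps from a free-breathing
  baseline (default 10 mm peak-to-trough — a typical quiet-breathing
  excursion; the phantom protocol does not print one).
* **Couch sag**: a smoothstep ($3u^2-2u^3$) deflection developing during
  table travel, to $-5$ mm at worst case. Helical mode deflects across its
  single beam-on block; axial 4DCT mode adds an equal increment during each
  table-feed gap. The three load scenarios (0, +52, +104 kg) scale the
  deflection by 0.2 / 0.6 / 1.0 — only the worst-case magnitude is
  anchored by measurement, the intermediate scaling is the package's own
  interpolation. The identical deflection rides under both markers.
* **X-ray schedule**: helical scans are one beam-on block (covering the
  final breath-hold in DIBH sequences); axial 4DCT runs 6 s beam-on blocks
  separated by 2 s feed gaps (the scanner's true axial timing is not
  published; these are round defaults).
* **Camera geometry**: patient-frame positions are embedded into global
  coordinates through the inverse pitch rotation (default
  $\theta = 0.35$ rad).
* **Tracking noise**: isotropic Gaussian noise per global axis, RMS
  0.06 mm (only the RMS figure is published, hence isotropy). Marker
  *orientation* noise is not modelled — the tracker's angular error is an
  order of magnitude below anything that matters here, and $\theta$ is a
  per-session median anyway.
* **Latency**: a constant 16.6 ms offset on the table stream; jitter is out
  of scope.

Because two independent noise channels enter the corrected signal, the
corrected residual has RMS $0.06\sqrt{2} \approx 0.085$ mm — a property the
test suite checks distributionally.

What the simulator does **not** emulate: anatomical deformation and
cardiac/irregular breathing components, couch mechanics beyond the
smoothstep time-course, imaging artifacts, and the patch-jump artifacts of
surface-imaging systems. Passing the in-silico suite therefore demonstrates
the correctness of the correction arithmetic and the metric definitions
under controlled conditions, not clinical performance on real patients.

Twelve `scenario_presets()` mirror the study grid: phantom DIBH / 4DCT
under three loads, and volunteer DIBH / 4DCT under audio guidance, visual
guidance, and visual guidance with table travel (the volunteer
table-travel presets use a clinically typical $-1.7$ mm deflection;
volunteer breath-hold level 15 mm and 6 s holds are representative choices,
as the per-volunteer values naturally varied).

## Problem sizes and reproducibility

Simulated sessions default to 60 s at 50 Hz (3001 frames per marker) —
enough for eleven breathing cycles or three breath-holds, comfortably
resolving every metric, and small enough that the hundred-run residual
study completes in seconds. Every simulation carries an integer seed;
identical seeds give byte-identical pose logs. `scripts/acceptance.R`
derives all of its per-run seeds from a single `--seed` argument.

## Known limitations

* The correction removes only the AP component of couch motion; roll and
  yaw are not corrected (pitch-only, like the source instrumentation).
* A constant AP offset between the two markers passes through to the
  corrected signal as a constant; all shipped metrics are
  translation-invariant, but absolute levels should not be over-read.
* The plateau detector's adaptive height gate assumes breath-holds are the
  dominant high-amplitude feature of the trace; traces that are mostly
  plateau with brief dips would need an explicit threshold.
* Volunteer-scenario presets reproduce the *conditions* (guidance mode,
  table travel), not inter-subject variability; cohort-level statistics on
  simulated volunteers would be optimistic.
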