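# breathtrace

Respiratory surrogate signals for CT with couch-motion correction.

External surrogate systems track a marker on the patient's chest to gate
4DCT acquisition or coach deep-inspiration breath-holds (DIBH). They cannot,
on their own, tell breathing from motion of the CT couch: table feed and
table *sag* under patient load leak into the measured signal, shifting 4DCT
amplitude bins and tilting breath-hold plateaus by several millimetres.
`breathtrace` implements the dual-marker fix — a rigid reference marker on
the couch, tracked alongside the patient marker — and everything needed to
evaluate it:

* **geometry** — camera pitch extraction `θ = arcsin(−R31)` from marker
  orientation matrices, the y-axis rotation into the patient frame, AP
  projections `x = x_g·cosθ + z_g·sinθ` for both markers, and the exact
  sample-wise correction `x_corrected = x_breathing − x_table`;
* **stream I/O** — plain-text pose logs and breathing-trace CSVs, pairing
  of asynchronous marker streams by linear interpolation, alignment at the
  first X-ray-on event, beam-on event extraction;
* **metrics** — DIBH plateau detection with mean-amplitude reproducibility
  and intra-hold drift (OLS slope, mm/s); 4DCT cycle segmentation
  (max-to-max) with per-cycle amplitude/duration statistics and the
  end-expiration **baseline shift**; cohort aggregation that reproduces
  published volunteer summary tables; normality-gated scenario comparison
  (paired t vs Mann-Whitney U);
* **feedback** — the cos⁶ guidance waveform `g(t) = A(1 − cos⁶(πt/T))`
  (A = 30 mm, T = 10 s by default), static and dynamic breathing windows,
  and green/yellow/red state classification;
* **simulator** — a full in-silico test bed: breathing patterns, load-scaled
  smoothstep couch sag (to −5 mm), camera pitch embedding, X-ray schedules,
  0.06 mm RMS tracking noise and table-stream latency, with ground truth
  returned alongside every run.

## Worked example

Simulate the worst-case phantom scenario (axial 4DCT, +104 kg couch load,
−5 mm sag, tracking noise on), run the correction, and compare corrected
vs uncorrected quality metrics:

```r
library(breathtrace)

cfg <- preset_config("phantom_4dct_104kg", seed = 42)
sim <- simulate_session(cfg)
res <- correct_session(sim)

res$corrected
#> <breathing_trace> corrected: 3000 samples, t = [0.020, 60.000] s, amplitude range [-0.20, 20.15] mm, 1500 beam-on

fourd_report(res$corrected)
#> <fourd_report> 11 cycles | amplitude 20.2 +/- 0.1 mm | duration 5.0 +/- 0.1 s | baseline shift 0.04 mm

fourd_report(res$uncorrected)
#> <fourd_report> 11 cycles | amplitude 20.4 +/- 0.5 mm | duration 5.0 +/- 0.1 s | baseline shift -4.96 mm
```

The generator injected a 0.2 Hz / 20 mm sinusoid riding on −5 mm of couch
sag. The single-marker (uncorrected) signal reports that sag almost in full
as a −4.96 mm baseline shift — exactly the failure mode that corrupts
amplitude-binned 4DCT — while the dual-marker corrected signal reduces it
to 0.04 mm, residual tracking noise only. Cycle amplitude and duration
(20 mm, 5 s) recover the generator's parameters.

Cohort aggregation of the bundled ten-volunteer DIBH summary values
(audio-feedback scenario, plateau amplitudes):

```r
d <- subset(volunteer_summaries("dibh"), scenario == "audio")
cohort_summary(d$amplitude_mean_mm, d$amplitude_sd_mm)
#> <cohort_summary> n = 10
#>   mean total: 12.6 ± 6.5
#>   mean SD:    1.1 ± 0.7
```

The same pipeline is scriptable from a shell via the installed
`exec/breathtrace` entry point (`simulate`, `correct`, `analyze`, `cohort`,
`feedback` subcommands; exit codes 0/2/3/4 for success / usage /
validation / undefined metric).

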