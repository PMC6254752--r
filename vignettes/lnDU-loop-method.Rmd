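---
title: "Local PWV from sequential ultrasound: the ln(D)U-loop method in pwvloop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local PWV from sequential ultrasound: the ln(D)U-loop method in pwvloop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwvloop)
```

## The model

Local pulse wave velocity (PWV, `c`) is the speed of the pressure/flow pulse
over a short arterial segment and a direct measure of local stiffness. When
only forward-running waves are present — early systole, before reflections
return from the periphery — water-hammer-type relations tie the increments
of flow velocity `U` and vessel diameter `D` together:

    dU = 2 c d ln D

so a plot of `U` against `ln D` over a cardiac cycle (the ln(D)U-loop) is
linear during early systole with slope `2c`, and

    PWV = (1/2) dU / d ln D.

Both quantities come from conventional ultrasound: `D` from an M-mode
recording across the ascending aorta (parasternal long-axis view), `U` from
pulsed-wave Doppler in the apical five-chamber view. The two cannot be
acquired simultaneously — there is no acoustic window that gives both — so
the central practical problem is pairing beats recorded minutes apart, at
slightly different heart rates, into loops that are aligned in time.

## The pipeline

1. **Image input** (`read_recording`). A recording is a cine whose frames are
   concatenated along the time axis into one continuous image; calibrations
   (ms/pixel, cm/pixel or m/s/pixel, Doppler baseline row, ECG strip rows)
   come from the sidecar. Because no DICOM reader is available in this
   toolchain, the package reads a documented plain-text dialect (frame
   matrices + JSON sidecar) that the synthetic module also writes; the
   module boundary is unchanged, so a DICOM front end would slot in before
   `us_recording()`.
2. **ECG** (`extract_ecg_trace`, `detect_r_peaks`). The strip trace is the
   intensity-weighted centroid of suprathreshold pixels per column; R-peaks
   are maxima between upward and downward crossings of a height-relative
   threshold (0.8 of the global min-to-max range), with a 200 ms refractory
   period against double detection.
3. **Tracing** (`trace_wall`, `smooth_trace`, `diameter_waveform`,
   `trace_doppler_envelope`). Walls are thresholded inside user-declared
   ROIs: the near wall keeps its deepest suprathreshold pixel, the far wall
   its shallowest — the inner, lumen-facing edges. An automatic artefact
   pass drops points more than 3 MAD from a rolling median (15-column
   window), with the scale floored at one quantization step so the pixel
   staircase of a steep upstroke is never thinned. A smoothing spline
   (csaps-convention `p = 0.001` on the pixel axis) smooths each wall trace
   and fills its gaps; `D` is far minus near in cm. The maximum Doppler
   envelope is the suprathreshold pixel farthest from the baseline on the
   forward-flow side, passed through the same spline.
4. **Beats** (`segment_beats`, `detect_upstroke_onset`, `select_groups`,
   `match_groups`). Beats span consecutive R-peaks. The upstroke onset is
   found by the backward regression search: starting from mid-systole
   (temporal midpoint of pre-peak minimum and peak) the segment grows
   downward point by point and the first candidate whose segment r² falls
   below 0.985 stops the search. Six-beat moving windows are formed, and
   for each D/U run pair the window pair with the most similar mean cycle
   duration is selected as representative.
5. **Loops** (`align_and_truncate`, `fit_loop`, `pwv_from_slope`,
   `all_pairings`). Each selected D beat is paired with each selected U
   beat (3 runs x 6 beats per side = 324 pairings). Both beats are
   interpolated to a 1 ms grid from their own onsets to their closing
   R-peaks; the longer tail (late diastole) is truncated, preserving
   systole. The early-systolic limb is fitted by forward growth from the
   onset while r² > 0.98; the slope of the last acceptable fit gives
   PWV = slope / 2. Non-positive slopes, unfittable loops, and fits
   spanning under 10 ms are QC-flagged and excluded.
6. **Ensemble** (`trimmed_mean_pwv`, `cohort_summary`). The 10% most
   extreme pairing-level PWV values (5% per tail, floor rounding) are
   excluded; the mean of the rest is the subject's PWV and their SD the
   within-subject SD.

## Parameters that matter

| key | default | unit | meaning |
|---|---|---|---|
| `ecg.threshold_fraction` | 0.8 | — | R-peak threshold as a fraction of ECG height |
| `ecg.refractory_ms` | 200 | ms | minimum R-R separation |
| `tracing.smoothing_parameter` | 0.001 | — | csaps `p` on the pixel axis; `1` interpolates |
| `tracing.*_threshold`, `*_roi` | sidecar | — | grayscale cutoffs and wall search bands |
| `beats.group_size` | 6 | beats | representative window length |
| `beats.upstroke_r2` | 0.985 | — | onset-search stopping threshold |
| `loop.dt_ms` | 1.0 | ms | common loop sampling grid |
| `loop.fit_r2` | 0.98 | — | loop-growth stopping threshold |
| `loop.min_fit_ms` | 10 | ms | shortest physiologically meaningful limb |
| `ensemble.trim_fraction` | 0.10 | — | total extreme fraction excluded |

The r² thresholds and the smoothing parameter are empirical constants of
the method, calibrated for thresholded ultrasound traces; they are
configurable but should not be tuned per subject.

## The synthetic world

`synthetic_subject()` states one physiologic world and the generator sticks
to it:

* diastolic diameter 2.6 cm with a 0.2 cm systolic distension — a healthy
  young-adult ascending aorta;
* a quarter-sine upstroke (120 ms rise) with exponential diastolic decay
  (220 ms time constant). The upstroke has a positive initial slope: the
  onset is the point where the waveform *begins to rise linearly*, which is
  the event the onset detector is defined to find. A zero-slope (e.g.
  raised-cosine) foot has no such point, and the detector's landing then
  drifts with trace smoothness — we use the shape that matches the method's
  own definition;
* velocity tied to diameter by `U = 2 c ln(D/D_d)` exactly, before
  reflections;
* a reflected wave 120 ms after the onset at 35% relative magnitude with a
  20 ms front, adding to `D` and subtracting from `U` so the loop turns off
  its early-systolic line promptly. 120 ms is the mid-to-late-systolic
  return time of the backward compression wave in young adults; the front
  is kept steep so that post-onset nonlinearity — the one property the
  validation needs — is sharply localized;
* heart rate 70 bpm with 3% beat-to-beat cycle variability and 2% amplitude
  variability; D and U runs draw independent beat trains (distinct
  sub-seeds), so cycle-length matching and tail truncation are genuinely
  exercised;
* rendering noise: white pixel speckle (SD 10 grayscale), sparse bright
  speckle (5e-4 of pixels), and a slow AR(1) wander of every rendered
  interface (SD 1 px, ~17 ms correlation) emulating speckle-decorrelation
  jitter of wall and envelope edges. The wander matters: it survives the
  0.001 spline the way clinical trace noise does, and the r² thresholds
  were calibrated for noisy traces.

What the generator does **not** emulate: beam physics (speckle statistics,
spectral broadening, attenuation), probe angulation error, respiratory
motion, arrhythmia, and vendor overlay graphics. A green end-to-end test
therefore establishes that the *analysis chain* recovers a known wave speed
from images with realistic geometry, calibration, quantization and trace
noise — not that the method is robust to every clinical degradation.

## Numerical choices

* Segment r² is the squared Pearson correlation, computed for all prefixes
  in one cumulative-sum pass; a constant-response segment counts as r² = 1
  (a horizontal line fits it exactly), a vertical segment as 0.
* The MATLAB-style smoothing parameter `p` maps to
  `stats::smooth.spline(lambda = ((1-p)/p) / diff(range(x))^3)` — verified
  against an independent raw-axis implementation and against the analytic
  attenuation `1/(1 + lambda * omega^4)` of a sinusoid.
* Interpolation to the loop grid is linear; the truncation end is anchored
  at the closing R-peak; pairs shorter than 10 samples are rejected.
* Trimming uses floor rounding per tail; `10%` total splits as 5% per tail
  (a per-tail variant is available by flag).
* The generator clamps its Gaussian draws at 3 SD so a single extreme draw
  cannot produce an unphysiological beat.

## Design decisions on open ground

* **Mid-systole** for the onset search is the *temporal* midpoint of foot
  and peak (the amplitude midpoint was the alternative); the index is kept
  on the beat for audit.
* **Run pairing**: representative groups are chosen per D-run/U-run pair,
  matching run *i* with run *i* — the runs are ordinal repeats of one
  protocol taken minutes apart, so the i-th runs are closest in time.
* **Fit-start correction**: when growth from the common onset cannot
  sustain a 10 ms limb, the start advances sample by sample (at most
  30 ms) to the first point from which the same growth rule sustains it.
  This automates the visual correction of automatic onsets and fits that
  an interactive workflow performs: the detected onset regularly sits a
  few samples inside the preceding diastolic tail, and a fit seeded inside
  that hook is either stunted or rotated. On clean loops the start stays
  at the onset and the rule is the textbook one. `start_index` on each
  `loop_fit` records any advance.
* **Automated QC replaces visual flagging**: `negative_slope`,
  `unfittable_loop` and `short_fit` loops are excluded before trimming and
  counted in the report.
* **Artefact exclusion** is config-declared intervals plus the rolling-MAD
  pass — a reproducible surrogate for interactive artefact removal.

## Known limitations

* **Smoothing-induced slope bias.** The prescribed spline (`p = 0.001` on a
  3.5 ms/px axis) has a half-power period of roughly 124 ms. It therefore
  smears any reflected front backwards by ~20-30 ms, shortening the
  *traced* reflection-free window, while the r² > 0.98 growth rule spends
  its whole acceptance budget on the smeared curvature and overruns the
  break. On rendered images this produces a structural underestimate of
  PWV of about 8-10% with the default synthetic world; the waveform-level
  path (no imaging) recovers wave speed within ~2-4%. The effect worsens
  for earlier reflections — with an 80 ms delay the underestimate reaches
  20-25%. This is a property of the published parameter set, faithfully
  reproduced, and the end-to-end recovery test asserts the 10% target
  regardless, so it fails visibly rather than silently.
* **Corners sharper than the spline passband.** A derivative discontinuity
  (the upstroke foot; an abrupt reflected front) cannot be tracked to
  sub-2-pixel accuracy by the prescribed smoothing; round-trip accuracy
  contracts are stated for band-limited waveforms, and raw (pre-spline)
  traces track rendered edges within 1 pixel.
* **Onset lag.** On smooth traces the backward r² search admits 2-4 foot
  samples before stopping, so detected onsets sit ~7-14 ms early. The lag
  is common to both waveforms (so loops stay aligned) and the fit-start
  correction absorbs what remains.
* The cine dialect is the package's own text format; clinical DICOM export
  requires an external conversion step.
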