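---
title: "Detecting quiescent cardiac phases in free-running MRI: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting quiescent cardiac phases in free-running MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the detection model and its assumptions, the simulation framework used to
validate it, the tunable parameters, and the design decisions that were
genuinely open.

## The detection model

Free-running 3D radial acquisitions sample k-space continuously over many
cardiac cycles. The package's task is to find, from the data alone, the
three clinically used quiescent phases — end-systole (ES), mid-diastole
(MD), end-diastole (ED) — and to turn them into per-beat data acceptance
windows whose center *and* width scale with each beat's own RR interval.

The core assumption is statistical: in a preliminary cardiac-resolved
(CINE) reconstruction, voxels at the endocardial border are blood (bright,
under bSSFP-like contrast) at end-diastole and myocardium (darker) at
end-systole, so their intensity time curves reach a *synchronous* minimum
at the phase of minimal cavity volume. Grouping voxels by the frame of
their minimum and by spatial 26-connectivity (faces, edges, corners)
produces a synchronicity map whose large regions trace moving cardiac
structures, while noise voxels and static anatomy fragment into small
regions. Two refinements isolate the left ventricle:

* **size ranking** — keep the top 25% of regions by voxel count;
* **physiological filter** — keep regions whose mean-curve extrema
  interval (maximum to minimum, in ms of the mean RR) is compatible with
  the expected ejection time at the subject's heart rate. The ejection
  time model is the linear regression `ET(ms) = a − b·HR(bpm)` with
  defaults `a = 546`, `b = 2.1` and ±30% acceptance margins. The same
  model drives the simulator's non-linear phase stretching, so the filter
  is exercised under exactly the physiology it assumes. The coefficients
  are a documented stand-in calibrated to the physiological literature's
  scale (ET ≈ 390 ms at 75 bpm); they are configurable in
  `sync_control()`, and in clinical use they should be set from the
  population at hand. The outflow tract, whose caliber varies out of
  phase with the LV, fails this filter — that is what the simulator's
  pulsating aorta tube is for.

On the averaged time curve of the surviving voxels, `t_ES` is the
minimum, `t_ED` the maximum, and `t_MD` the circular midpoint between
`t_ED` and the *first knee* after `t_ES` — the end of rapid filling. The
knee is the point of maximum perpendicular distance to the chord from the
minimum to the maximum (a Kneedle-style rule; the method literature names
the knee but not an algorithm, so the chord rule is this package's
choice: it is parameter-free and robust on 50-frame curves).

Quiescent intervals grow around each timepoint while the normalized curve
stays within ±3% of its value there; while an interval lasts ≥ 200 ms
(via the mean RR), the threshold is lowered by 0.25% per iteration — the
200 ms cap follows standardized whole-heart protocol recommendations, and
the 0.25% step is this package's discretization of "iteratively
lowered". A strictly V-shaped curve yields the minimal one-frame
interval; if the threshold reaches zero on a perfectly flat curve the
single-frame fallback is returned with a warning.

### Reference frames

Self-gating beat onsets are rising zero crossings of the cardiac
self-gating signal. Their offset to the true R-wave is unknown and is
*not* estimated: only beat-to-beat intervals are meaningful, and all
phases produced by the pipeline live in this internal frame. For
validation the package converts detected phases into the simulated-ECG
frame (`phase_in_reference_frame()`): each beat's absolute time of the
detected phase is re-normalized against the ground-truth beats and the
per-beat phases are combined circularly. Both the detected timepoint and
the interval-center estimator are exposed, since reported validations in
this field use either.

## The simulation framework

The simulator emulates a dynamic-phantom-based validation without any
external data:

* **Volume curve.** A periodic spline through fixed control points: ED
  peak (120 mL) at phase 0, ES trough (50 mL) at 36%, rapid filling, a
  mid-diastolic plateau, an atrial kick. Ten variants perturb the plateau
  level (103–107.5 mL), slope (0–0.225 mL per % phase) and extent;
  variant 0 is the flattest. The variants are parametric perturbations,
  not replicas of any published curve set.
* **Beats.** RR intervals are i.i.d. Gaussian with mean `rr_base_ms` and
  SD `hrv_ms` (the definition of HRV used throughout), truncated to
  `[max(300, rr−3·hrv), rr+3·hrv]` to exclude non-physiological beats.
* **Stretch.** Within each beat, the systolic sub-interval has the
  duration predicted by the ejection-time model at that beat's rate and
  maps linearly onto [0, 36%] of curve phase; diastole takes the rest.
  Cardiac phase is therefore non-linear in the beat fraction, and more so
  for short beats.
* **Phantom.** Analytic ellipsoids and tubes (torso, LV cavity inside an
  incompressible myocardial shell whose wall volume is conserved,
  pulsating aorta, coronary-analog tube). For each of the 50 phases the
  cavity is rescaled so its *voxelized* volume matches the curve — the
  radius scale is found by exact inversion on the sorted ellipsoid
  quadratic form, which is the fixed point a bisection would converge to.
  Labels become signal via the on-resonance bSSFP steady state
  `S = PD·sin α / ((T1/T2 + 1) − cos α (T1/T2 − 1))` (flip 60°; blood
  T1/T2 1660/240 ms, myocardium 870/45 ms, soft tissue 900/50 ms).
  The vessel tube (radius 7 mm) rides the atrioventricular-groove motion
  by scaling its centerline about the heart center with the cavity
  radius scale; its radius is exaggerated relative to a real coronary so
  that it spans ≥ 1.5 voxels at desk-scale resolution.
* **Sampling.** Spiral phyllotaxis directions (golden-angle azimuth,
  square-root polar spacing, interleaved shots) with the first segment of
  every shot replaced by a superior-inferior line — one self-gating
  sample per shot. Each line is extracted from the nearest of the 50
  phase volumes by a gridding NUFFT. No respiratory motion, no noise
  beyond the sampling/streaking itself, single coil: the simulation
  isolates cardiac-motion effects, so passing tests say nothing about
  robustness to breathing, flow dephasing, off-resonance or coil
  combination on real data.

## Numerical choices

* **NUFFT.** 2× oversampled Cartesian grid, trilinear interpolation
  expressed as an explicit sparse operator, so the forward and adjoint
  maps are exact transposes (adjoint test residual ~1e−15). The gridded
  reconstruction applies |k|² radial density compensation (the k = 0
  sample gets the analytic small-volume weight Δk²/12) and image-domain
  sinc⁻² deapodization. The density compensation is an assumption — the
  reference pipeline does not state its choice.
* **CINE weights.** Gaussian kernel with σ = 5% of the cycle ("width
  5%" is read as σ; the FWHM reading would halve the effective
  smoothing — σ is kept as the documented, configurable default). Each
  frame's weights are normalized to unit sum so frame intensity does not
  depend on how many lines happen to fall near the frame center; without
  this the per-voxel time curves carry a sampling-density ripple.
* **Ties and degenerate inputs.** Argmin ties break to the lowest frame;
  voxels below 20% of the global mean intensity are invalid; regions
  under 10 voxels are noise; an all-rejected physiological filter and a
  flat mean curve (range < 5% of its mean) are detection failures with
  diagnostics, not silent results.
* **Problem sizes.** The desk-scale protocol is matrix 48, 600 shots ×
  22 segments, FOV 220 mm, TR 5.38 ms (~71 s of simulated scan, ~90
  beats at RR 800). 600 shots matter: at 500 the preliminary CINE showed
  a coverage ripple on the diastolic plateau at low HRV that destabilized
  the knee detection. The full-scale protocol (matrix 192, 5749 shots) is
  retained for trajectory-level checks. The validation grid used in the
  tests is 3 RR (650/875/1100 ms) × 3 HRV (30/90/165 ms) × 2 curve
  variants; the full published-style grid (10 × 10 × 10 = 1000) is
  enumerable and runnable through the same code path.

## Known limitations

* The temporal error of `t_MD` is structurally larger than `t_ES`'s: the
  plateau is long and flat, so the midpoint-of-knee-and-ED rule can land
  tens of ms from the plateau center without any volumetric consequence —
  the volumetric error stays small precisely because the plateau is flat.
  The interval-center estimator shows the same pattern.
* The ±3% amplitude band is a single threshold for all three phases; the
  ES interval is accordingly much shorter than the MD interval, and the
  amount of accepted data (hence noise/streaking in the selected
  reconstruction) varies between datasets.
* Vessel sharpness via maximum edge derivative is upward-biased by streak
  noise when few lines are selected; comparisons between window
  strategies should therefore average over curve variants, as the grid
  experiment does.
* The self-gating-to-R-wave offset is unresolved by design; absolute
  trigger delays cannot be reported, only phases within the self-gating
  frame (or a reference frame when one exists).
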