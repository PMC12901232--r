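# cardiosync

Automated, heart-rate-variability-adaptive detection of quiescent cardiac
phases — end-systole (ES), mid-diastole (MD) and end-diastole (ED) — in
free-running 3D radial cardiac MRI, with the numerical simulation framework
needed to validate it end to end.

## The problem

Whole-heart MRI needs data from a quiescent cardiac phase in every
heartbeat. Conventional ECG-triggered scans fix a trigger delay and
acceptance window in milliseconds before the scan; when the heart rate
varies, a fixed window drifts out of the intended phase and the images
blur. Free-running acquisitions instead sample continuously and select the
data retrospectively — which makes it possible to place an acceptance
window *per beat*, with a center and width that adapt to each beat's own
RR interval, if the quiescent phases can be found automatically.

## The method

Given raw free-running 3D radial k-space with repeated superior-inferior
(SI) readouts:

1. **Self-gating.** SI projections are reduced by PCA; the component with
   dominant spectral power in the cardiac band (0.7–3 Hz) is the cardiac
   self-gating signal. Rising zero crossings mark heartbeats, and every
   readout timestamp is normalized to a cardiac phase in [0, 100)%.
2. **Preliminary CINE.** 50 frames are reconstructed by a gridding NUFFT,
   each frame weighting all lines with a Gaussian kernel (σ = 5% of the
   cycle) centered on the frame's phase.
3. **Synchronicity map.** Each voxel is labeled with the frame of its
   intensity-curve minimum; voxels with the same label are grouped by
   26-connectivity. Noise and static anatomy fall apart into small regions
   and are discarded.
4. **Refinement.** Only the largest regions (top 25%) survive, and regions
   whose extrema interval (curve maximum to minimum, in ms of the mean RR)
   is incompatible with a parametric systolic-interval model
   `ET = a − b·HR` (defaults a = 546 ms, b = 2.1 ms/bpm, ±30% margins)
   are rejected — separating the left ventricle from e.g. the outflow
   tract.
5. **Timepoints, intervals, windows.** On the averaged LV time curve,
   t_ES = minimum, t_ED = maximum, and t_MD = circular midpoint between
   the first knee after t_ES (maximum chord distance, Kneedle-style) and
   t_ED. Around each timepoint a quiescent interval grows while the curve
   stays within ±3% of its value there; the threshold is lowered in 0.25%
   steps until the interval lasts < 200 ms via the mean RR. Intervals map
   back to per-beat acceptance windows: `[onset + start%·RR_b,
   onset + end%·RR_b]` for every beat `b`.

The simulator provides the matching ground truth: a beating analytic torso
phantom (LV cavity in an incompressible myocardial shell, pulsating
outflow tract, coronary-vessel-analog tube riding the atrioventricular
groove) driven by a parametric LV volume curve, i.i.d. truncated-Gaussian
RR jitter, non-linear systole/diastole phase stretching, bSSFP contrast,
and NUFFT sampling along a spiral phyllotaxis trajectory.

## Worked example

```r
library(cardiosync)

ds <- simulate_freerun(rr_base_ms = 800, hrv_ms = 0, variant_id = 0, seed = 1)
fit <- quiescence(ds)
fit
#> Quiescent cardiac phase detection (selfgating beats)
#>   88 beats, mean RR 800 ms (HR 75 bpm)
#>   ES: t =  23.2% ( 186 ms), interval   4.0% ( 32 ms)
#>   MD: t =  60.6% ( 485 ms), interval  20.0% (160 ms)
#>   ED: t =  79.2% ( 634 ms), interval  20.0% (160 ms)
validate_detection(fit, ds)
#>   phase detected_pct truth_pct temporal_error_ms volumetric_error_pct interval_ms
#> 1    ES    45.519507  48.56250         -24.34395            2.0245889     32.0038
#> 2    MD    82.951166  75.88867          56.49995            0.4151594    160.0190
#> 3    ED     1.568397   0.00000          12.54718            0.0800558    160.0190
```

The timepoints are reported in the self-gating beat frame; the validation
maps them into the simulated-ECG frame before computing errors. Note the
classic pattern: the mid-diastolic *temporal* error is the largest (the
plateau is long and flat, so the exact timepoint is poorly determined),
while its *volumetric* error is the smallest — the detected window sits
comfortably on the plateau. All three intervals respect the 200 ms cap.

A full comparison of the automated adaptive windows against
manually-parameterized fixed and adaptive reference reconstructions,
including coronary vessel sharpness, runs with:

```r
res <- grid_experiment(grid_configs("desk"))   # 18 simulated datasets
summarize_grid(res)
compare_strategies(res, "vs_full")
```

## Command line

A thin CLI over the package functions lives in `inst/cli/cardiosync`:

```sh
Rscript inst/cli/cardiosync simulate --rr 800 --hrv 30 --variant 0 --seed 1 --out ds.rds
Rscript inst/cli/cardiosync detect --in ds.rds --report report.json
Rscript inst/cli/cardiosync recon --in ds.rds --strategy auto --phase MD --out md.nii.gz
Rscript inst/cli/cardiosync grid --scale desk --out results.csv
```
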