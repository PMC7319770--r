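---
title: "Quantification methods in dopaquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods in dopaquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dopaquant)
```

`dopaquant` quantifies striatal dopamine release from three kinds of data:
carbon-fiber amperometry traces, 3D structured-illumination image volumes of
dopaminergic axons, and 2D synaptosome immunofluorescence fields. Every
analysis stage has a matching ground-truthed synthetic generator, so the
whole chain can be validated end to end without acquired data. This vignette
documents the quantitative conventions the package commits to and the
assumptions behind them.

## Amperometric trace metrics

### Calibration and conversion

Electrodes are calibrated against known dopamine standards with a linear
fit. `fit_calibration()` refuses fits with r² below 0.98: a fouled or drifting
electrode must be recalibrated, not analysed. `current_to_concentration()`
inverts the fitted line to express a recorded current trace in µM.

```{r calibration}
cal <- fit_calibration(concentration_um = c(0.5, 1, 2, 4),
                       current_na = c(1.02, 1.99, 4.05, 7.98))
cal$r_squared
```

### Event metrics

Given a trace in concentration units, a pre-stimulus baseline window and a
search window:

* **Peak amplitude** (`peak_amplitude()`) is the maximum baseline-subtracted
  concentration in the search window.
* **20–80% rise time** (`rise_time_20_80()`) is the time between the 20% and
  80% crossings of the peak level, with the peak level read from a 1 ms
  moving average so a single noise sample cannot define 100%. Crossing times
  are linearly interpolated between samples.
* **Area under the curve** (`area_under_curve()`) integrates the
  baseline-subtracted trace by the trapezoid rule over a fixed window after
  stimulus onset, 2.935 s by default; a fixed window keeps areas comparable
  across conditions with different decay kinetics.

Electrical stimulus artefacts are removed before metric extraction by
`remove_stimulus_artefacts()`, which blanks a short window (default 1 ms)
at each onset and bridges it by linear interpolation. Acquisition hardware
low-pass filters the signal at 400 Hz; the package treats that as a property
of the recording (`lowpass_trace()` can emulate it on synthetic data, and is
not applied anywhere in the analysis chain by default).

### Trains, uptake block, KCl, microdialysis

* `train_amplitudes()` measures each response in a stimulus train relative
  to the trace value immediately before its onset, so summating responses
  are not double-counted, and normalizes by a reference first amplitude
  (in genotype comparisons, the control group's mean first amplitude).
* `dat_block_comparison()` compares the same integration window before and
  during dopamine-transporter block, reporting both the subtracted area
  (drug − baseline) and the fold increase (drug / baseline).
* `kcl_response()` measures a KCl puff as the peak and area from puff start
  to 200 s after the puff ends, against a pre-puff baseline.
* `normalize_microdialysis()` divides in vivo dopamine levels by the mean
  over a 76–120 minute reference window and also returns a natural-log
  copy, matching the lognormal behaviour of such series.

## 3D axon volumes

`analyze_roi()` runs the full volume pipeline on a two-channel
`image_volume` (axon marker + release-site clusters):

1. **Otsu segmentation** (`otsu_threshold()`): each channel is thresholded
   at the 256-bin histogram cut maximizing between-class variance.
2. **Connected components** (`label_components()`): 26-connectivity in 3D.
3. **Size windows** (`size_filter()`): axon components are kept between
   0.04 and 20 µm³ and cluster components between 0.003 and 0.04 µm³,
   rejecting speckle below and fused masses above each window.
4. **Classification** (`classify_in_axon()`): a cluster is *in-axon* when
   strictly more than 40% of its voxels lie inside the axon mask.
5. **Axon metrics**: the TH volume fraction is the axon-mask voxel
   fraction; axon length is measured by Gaussian pre-smoothing, homotopic
   thinning to a one-voxel skeleton, and summing the physical edge lengths
   of a minimum spanning tree over the skeleton's 26-adjacency graph
   (`skeletonize_axons()`), divided by the region volume.
6. **Local-shuffle null** (`shuffle_null()`): each detected cluster is
   independently re-dropped uniformly inside the 1×1×1 µm box centred on
   its position, 1000 rounds by default; the shuffled in-axon density and
   mean in-axon cluster volume quantify what colocalization chance alone
   would produce at the same local cluster density.

### Operating envelope of the thresholding step

Otsu's criterion assumes the histogram is meaningfully bimodal. When the
foreground occupies a very small fraction of the volume and the background
is noisy, the variance-maximizing cut can land inside the noise
distribution instead of between noise and signal; no global threshold is
reliable in that regime. The synthetic volume generator therefore
guarantees scenes inside the envelope (axons are walked to a target length,
1.5× the longest volume extent by default) and the same care is required of
acquired data: crop regions so that the structure of interest is not
vanishingly sparse.

## 2D synaptosomes

`analyze_synaptosomes()` processes registered Bassoon / TH / Syt-1
channels:

1. background subtraction with a 1 µm rolling ball
   (`rolling_ball_background()`);
2. punctum detection per channel (`detect_puncta()`): Otsu threshold,
   area window 0.2–1 µm², and a bounding-box side ratio below 1.5 to
   reject debris and fibres;
3. category assignment (`categorize_objects()`): overlapping Bassoon and
   TH puncta pair into Bassoon+TH+; unpaired puncta count as Bassoon+TH−
   or Bassoon−TH+;
4. Synaptotagmin-1 positivity: an object is Syt-1 positive when Syt-1
   covers between 20% and 100% of its area, both bounds inclusive.

## Synthetic generators

* `generate_trace()` builds traces from the difference-of-exponentials
  transient `A·k·(exp(−t/τ_decay) − exp(−t/τ_rise))`, peak-normalized so
  `A` is the true peak. Truth values (peak, 20–80% rise time, windowed
  area) come from the closed form, not from re-measuring the samples, so
  recovery tests are against analytic ground truth. Optional stimulus
  artefacts, Gaussian noise and a linear electrode model produce the
  current trace.
* `generate_volume()` renders axons as fixed-radius tubes around random
  walks with Gaussian angular jitter. Walks reflect off the volume faces —
  an imaged region intersects axons that continue beyond it — and lay down
  a target length (`axon_length_um`). Release-site clusters are ellipsoids
  placed on the axons or as a Poisson process outside them; placement
  rejects renders that touch an existing cluster (which would merge two
  planted objects into one component) and renders that retain less than
  half or more than double their requested volume (a discretization
  artefact at small sizes). Default voxels are 0.125 µm axially and
  0.04 µm laterally, typical of the acquisition class the pipeline
  targets. Degradation is separable Gaussian blur plus additive Gaussian
  noise.
* `generate_puncta_field()` plants elliptical puncta by category with
  known Syt-1 positivity, plus deliberately oversize and elongated objects
  for testing the filters.

Noise in all generators is Gaussian; detector-specific noise (Poisson
photon statistics, line artefacts) is out of scope, so recovery tolerances
established on synthetic data are necessary, not sufficient, evidence for
a given acquisition.

## Reproducibility

`run_stage()` dispatches each pipeline stage with a parameter list and a
master seed; each stage derives an independent stream via `derive_seed()`
and writes its outputs deterministically, so any stage can be rerun
bit for bit. `write_report()` emits tidy `(run_id, item_id, metric, value,
units)` tables sorted deterministically, with a JSON run record (stage,
parameters, seed, package version) alongside. The numbered scripts under
`analysis/` chain the stages into the full workflow.

```{r run-stage, eval = FALSE}
run_stage("simulate-trace",
          params = list(duration_s = 1, stimulus_times_s = 0.1),
          seed = 7L, out_dir = "results/raw/trace")
```
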