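---
title: "Simulating and analyzing loop-swapped (DIANA) fMRI acquisitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and analyzing loop-swapped (DIANA) fMRI acquisitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dianasim)
```

## What the package models

Direct Imaging of Neuronal Activity (DIANA) seeks millisecond-scale MRI
signal changes time-locked to neuronal events. The acquisition is a rapid
spoiled gradient-recalled echo (SPGRE) sequence with its *phase-encoding*
and *measurement* loops swapped: each stimulus trial (one stimulus plus one
interstimulus interval, M time points at TR spacing) samples a single
k-space line at all M time points; N consecutive trials fill the N lines of
each of the M images. One fully sampled "run" therefore takes N x M x TR,
and the putative functional response — a percent-scale, sub-second signal
change — is carried by the *temporal modulation of individual k-space
lines*, trial-averaged by construction.

Claims about such an acquisition (how drift manifests, what the per-trial
normalization removes, what amplitude a trial-averaged analysis can detect
at a given temporal SNR) are hard to test on scanner data alone. `dianasim`
re-creates the whole chain on a digital phantom so that every step can be
exercised against known ground truth: a Bloch engine, a synthetic-data
generator, acquisition schedules and k-space sampling, reconstruction with
2D rigid motion correction, and the trial-averaged statistical analysis.

## Steady state and dummy-pulse planning

Under perfect spoiling the longitudinal magnetization obeys, per excitation,

    Mz <- 1 + (Mz * cos(alpha) - 1) * exp(-TR/T1),

whose fixed point is the Ernst equilibrium `Mss = (1 - E1)/(1 - E1 cos
alpha)`, `E1 = exp(-TR/T1)`. `dummy_pulses_to_steady_state()` iterates this
recursion from full relaxation and reports, per T1, the first excitation
within a relative tolerance of `Mss`.

Two choices here are ours and are configurable, because the quantities they
feed are usually reported without them:

* **Convergence tolerance** `rel_tol`, default 1% of `Mss`. It is a required,
  logged parameter of the planning call.
* **T1 grid**, default 1000–4500 ms in 500 ms steps, spanning white matter
  through CSF at 7 T.

```{r}
plan <- dummy_pulses_to_steady_state(seq_params(tr_ms = 5, fa_deg = 4))
plan$table
plan$max_n_dummy
```

At TR = 5 ms and FA = 4 degrees the count grows from ~520 (T1 = 1000 ms)
past 1500 at the very top of the grid: the 1% criterion crosses 1500 dummy
pulses between T1 = 4300 and 4400 ms, so the exact count reported for a
"1000 to 1500" planning range depends on where the grid stops. The curve
convention is that index 0 is the fully relaxed pre-pulse state.

The full Bloch route, `simulate_rf_spoiled_ensemble()`, propagates an
ensemble of isochromats (default 500) with a uniform 2*pi intravoxel
spread of gradient-spoiler phase per TR (an ideal spoiler) and quadratic RF
phase cycling (default increment 50 degrees, the standard well-spoiled
regime). It is the cross-check that the fast longitudinal recursion is the
right tool for dummy planning: with 50-degree cycling the converged signal
sits within a few percent of the ideal-spoiling value `sin(alpha) * Mss *
exp(-TE/T2*)`, and with spoiling disabled and transverse magnetization
crushed it reduces to the recursion to 1e-6. B1 inhomogeneity, slice
profiles, magnetization transfer and diffusion effects on spoiling are out
of scope.

## The digital phantom and what it emulates

`make_default_phantom()` builds a 2D label map (96 or 192 square) with
7 T-like compartments (WM: T1 1200 ms, T2* 26 ms, PD 0.70; GM: 2000/33/0.80;
CSF: 4300/100/1.00) in two presets: a brain-like slice with CSF rim, cortical
gray-matter ribbon and white-matter core, and a tube phantom with four
distinct-T1 compartments for stability experiments. The geometry is placed
slightly off the grid center: an exactly symmetric object has k-space rows
that vanish identically, which is both unrealistic and degenerate for
per-line normalization. The brain preset carries a posterior-midline target
ROI (`target_v1`), a gray-matter control ROI with *exactly* the target's
voxel count (equated statistical power), and a white-matter control ROI.

Per-voxel signal is composed as

    baseline * (1 + response) * drift + baseline * physio + thermal

* **baseline** `pd * sin(alpha) * Mss(T1) * exp(-TE/T2*)` — the ideal-spoiling
  steady state; transients before the dummy period are not simulated, which
  is why the dummy planning module exists.
* **response**: a phenomenological percent-change boxcar (or half-sine) with
  amplitude, onset and duration in ms, applied multiplicatively inside a
  named ROI. Defaults (0.05%, onset 75 ms, duration 150 ms) follow the
  candidate signals that motivated the pipeline. No biophysical mechanism is
  implied — the mechanism is unknown — so the generator only provides ground
  truth for recovery tests.
* **drift**: linear multiplicative, `1 + rate * t / 60 / 100` with `rate` in
  %/min, identical in all voxels, continuous across run boundaries (this is
  what makes the inter-run step reproducible).
* **noise**: white thermal noise with SD as a percent of each voxel's
  baseline (so a 0.1% SD means voxel tSNR 1000), plus optional additive
  sinusoids for slow physiological fluctuation. The default noise model is
  silent so that null data are exactly null; `physio_default()` provides a
  0.3 Hz respiratory + 1.0 Hz cardiac pair at 0.05% each. These components
  are plausibility placeholders, not measured spectra.
* **motion**: per-trial 2D rigid parameters, fixed tables or a seeded random
  walk. Within a trial (<= 0.7 s) the head is assumed still.

What the phantom does *not* emulate — and therefore what passing tests do
not show about real data: through-plane motion (uncorrectable for a single
slice), inflow and saturation effects, EPI distortion, coil sensitivities,
partial-volume anatomy, eye blinks, and any genuine neuronal contrast
mechanism. Green recovery tests mean the *pipeline* is calibrated, not that
the scanner experiment would detect a response.

## Acquisition schedules and sampling

`diana_schedule()` (loop-swapped) and `spgre_schedule()` (conventional)
produce explicit event tables — (phase line, time point, trial, absolute
time) with times advancing by TR — so timing claims are checked against the
schedule, not re-derived. Phase lines default to sequential
(bottom-to-top) ordering; centric ordering is available because the
k-space-center timing controls drift sensitivity, but the published
protocol does not state an ordering. Stimulus onset is anchored at trial
phase 0 (the scanner and paradigm are trigger-synchronized); the
trigger-to-first-excitation offset is taken as zero and is configurable via
schedule start times.

`simulate_acquisition()` evaluates the phantom's instantaneous image at
each event's absolute time and trial phase, applies the trial's rigid
motion, and stores one full row of the 2D DFT. Sampling one row from a
static-in-readout image ignores intra-readout dynamics, which is safe at
650–810 Hz/pixel readout bandwidths where the readout is a small fraction
of the 5 ms TR. The readout direction is fully sampled at the matrix size
(square k-space, no partial Fourier). Parallel imaging is not simulated:
the high-resolution protocol preset generates the fully sampled 192 matrix
instead (a documented deviation; accelerated reconstruction and g-factor
noise are out of scope).

Where no per-voxel noise or motion is requested the sampler uses an exact
linear decomposition (DFTs of the baseline image and of the
response-carrying voxels, scaled per event), so large noise-free protocols
cost two FFTs.

## Drift: ramp versus step, and per-trial normalization

The image mean is dominated by the k-space center. A conventional SPGRE
series crosses the center every N x TR, so slow drift reads out as a ramp
across images. The loop-swapped sequence crosses the center M times within
one trial and then not again until N x M x TR later: drift becomes a step
between runs, of size rate x N*M*TR.

Each trial contributes one line, so "normalizing each trial by its mean
signal" acts per line: `normalize_trials()` divides every sample of line n
by the mean over the M time points of the line's root-sum-square magnitude.
This removes a trial-wise drift scale exactly for a static object; the
small *within-trial* drift residual is linear in time and is absorbed by
the later detrending step. Dividing a line by its own magnitude whitens the
k-space profile, so `normalize_scan()` — the form used by
`run_experiment()` — re-scales each line to its across-run mean factor:
trial-wise scale (including the inter-run step) is removed while the image
structure is preserved. An image-domain normalization alternative would
divide each reconstructed run by its mean; the k-space reading is the
default because one trial is not voxel-separable after reconstruction.

## Reconstruction and motion correction

Reconstruction is the 2D inverse DFT per time point plus magnitude;
undersampled input is an explicit error. Optional 16-bit quantization
(scale = run maximum) mimics offline reconstruction with 16-bit dynamic
range; it is off by default since it is a fidelity stressor, not a
correctness requirement.

Motion correction registers every image to a reference (by default the
temporal mean of the designated run — which run the original procedure
averaged is unstated; we default to the first retained run). The estimator
is phase correlation for the integer translation, refined by Nelder-Mead
over (dx, dy, theta) on the sum of squared differences, with bilinear
resampling and zero fill (the slice background is air). Accuracy contracts
rather than a specific solver are the requirement: known transforms up to
2 px / 2 degrees are recovered within 0.1 px / 0.1 degree on noise-free
images, and a sigma = 0.2 px random walk corrects to below 0.1 px RMS
residual. Degenerate (constant) images return the identity with a `failed`
flag, and failures propagate in the transform log, never silently.

## The statistical chain

The per-run analysis order is fixed: percent signal change (baseline = the
voxel's temporal mean over the run) -> linear detrend (slope removed, mean
kept) -> Gaussian temporal smoothing -> ROI average. Runs are the
exchangeable unit: the mean time course and 95% confidence intervals use
the t distribution across runs, and group results pool all runs from all
subjects. The suite includes an order guard: permuting the stages changes
the output, so a silent reordering cannot pass.

Numerical and estimator choices:

* **Smoothing kernel**: "width = 3 time points" is read as a 3-tap kernel;
  sigma = 0.6 time points concentrates the mass on 3 taps (weights about
  0.23/0.54/0.23). Boundaries are reflective. Both are configurable.
* **Amplitude attenuation is intrinsic.** Because the percent-change
  baseline includes the response samples (factor `1 - k/M` for a boxcar
  covering k of M points) and the detrend line tilts toward an early
  response, the chain's peak output for a 75–225 ms boxcar in a 700 ms
  trial is ~0.65 of the injected amplitude — deterministically, with zero
  noise. The unit tests pin this transfer against a closed-form oracle, and
  recovery tests benchmark the estimator against its noise-free output
  rather than pretending the chain is unit-gain.
* **Response characterization** (`estimate_response()`) is descriptive, not
  inferential: amplitude is the peak of the smoothed mean after stimulus
  onset; onset is the first time point opening a run of at least 3
  consecutive points whose lower CI bound exceeds zero; duration is that
  contiguous supra-zero extent. The 3-point consecutivity requirement
  exists because the pointwise 95% bounds are uncorrected: with ~140 time
  points, a single-point rule flags noise in almost every null dataset,
  while 3 consecutive points keep null detections below a few per mille
  without biasing the onset.
* **Temporal SNR**: per-voxel mean/SD over the run's M time points;
  zero-variance voxels are flagged, not infinite. Under i.i.d. voxel noise
  the ROI-mean time course improves by sqrt(V), and
  `min_detectable_pct()` converts that into a detection limit,
  `(z_{1-alpha/2} + z_{power}) / (tsnr * sqrt(V * n_runs)) * 100` percent,
  under documented i.i.d. assumptions. At voxel tSNR 1000, V = 25 and 30
  runs this sits near 0.01%, which is why candidate signals of 0.02–0.05%
  are "close to the detection limit".
* **Fourier localizer**: block-design BOLD data (default 5 s on / 7 s off,
  TR 1 s) are screened in the frequency domain: the statistic projects each
  voxel's amplitude spectrum at the paradigm fundamental and harmonics onto
  the spectrum expected from the boxcar convolved with a canonical
  double-gamma HRF (peak 6 s, undershoot 16 s, ratio 1/6 — the procedure
  does not parameterize it, so the standard values are used), normalized by
  off-harmonic power. The detection threshold is calibrated on simulated
  white noise to a 5% voxelwise false-positive rate, since no published
  threshold exists for this screening step.

## Reproducible experiments

`experiment_config()` / `load_config()` / `save_config()` round-trip a full
experiment description through YAML; unknown fields are rejected by name.
`run_experiment()` simulates consecutive runs (drift continuous across
boundaries), normalizes, reconstructs, optionally motion-corrects, discards
the first run of each scan before trial averaging (residual transients can
survive the dummy period, so the first run is treated as a settling run),
analyzes every phantom ROI, and writes NIfTI/TSV/JSON artifacts, each
stamped with the config's MD5 hash. Everything is deterministic given the
config seeds.

## Problem sizes used in the test suite

The suite runs the full chain at reduced size where full protocols add
nothing: drift and reconstruction oracles use a 32-matrix phantom with
M = 40 (the step/ramp arithmetic is size-exact either way); statistical
calibration and recovery use ROI-level simulation at M = 140, V = 25,
voxel tSNR 1000, 30–90 runs, matching the regime the full protocols
produce; registration uses 48-pixel smooth images. Full 96 x 140 runs are
exercised end-to-end in the configuration tests. Timing and dummy-pulse
arithmetic are computed at protocol scale, since they are closed-form.

## Known limitations

Single slice only; no through-plane motion; no parallel imaging or EPI
readout; no inflow/saturation physics; the functional response is a
phenomenological percent-change pulse, not a biophysical model; the
physiological-noise defaults are placeholders; and the response
characterization inherits the descriptive (uncorrected) confidence-interval
usage of the underlying procedure.
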