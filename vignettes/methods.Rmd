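---
title: "Measuring skin surface roughness from OCT volumes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring skin surface roughness from OCT volumes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Optical coherence tomography (OCT) images skin as a stack of cross-sectional
B-scans, each column of which (an A-scan) is a depth-resolved intensity
profile. The air–skin interface appears as a sharp intensity step, so a 3D
OCT volume implicitly contains a topographic map of the skin surface. Two
ISO-style texture statistics summarize that topography:

* **Arithmetic mean roughness** — the mean absolute height about the mean
  surface over the evaluation region,
  `Ra = (1 / (nx * ny)) * sum |z(x_i, y_j)|`;
* **Depth of roughness** — the peak-to-valley height,
  `Rz = max(z) - min(z)`.

Both are defined on heights referenced to the *mean* surface. Skin, however,
is not flat at the centimetre scale: the back of a hand has a natural
curvature that dwarfs the texture-scale fluctuations. `octskin` therefore
runs a four-stage chain per volume: segment each B-scan into skin and
background, read the boundary off the mask, remove the per-B-scan curvature
with a second-order least-squares fit, and evaluate Ra/Rz on the assembled,
zero-mean 2D height map. Two auxiliary optical parameters are estimated from
the same data: epidermal thickness (first peak-to-valley interval of the
surface-aligned mean depth profile) and the dermal attenuation coefficient
(log-linear fit of the mean signal below the dermo-epidermal junction).

## The synthetic phantom: what it emulates and what it does not

No scanner is attached to this package; instead `phantom_spec()` +
`render_volume()` simulate layered skin volumes with exact ground truth so
every stage can be validated:

* a **surface height field** (flat, sinusoid, triangular grooves, or a
  Gaussian-correlated random field for skin-like texture), zero-mean by
  construction, with its grid-exact Ra/Rz stored as truth;
* an optional **global quadratic curvature** `z + c (x - x0)^2` per B-scan,
  applied *after* the truth roughness is recorded (curvature must not change
  true texture);
* a layered **intensity model** per A-scan: background noise floor above the
  surface; a bright entrance band rising to a peak 8 μm below the surface;
  a smooth decay to an intensity valley at the dermo-epidermal junction
  (DEJ); below it, a dermal signal decaying as `exp(-2 μ z)` (round-trip
  single-scattering);
* optional fully developed **multiplicative speckle** (each voxel multiplied
  by an independent Exp(1) deviate), the standard worst-case noise model for
  coherent imaging.

Defaults mirror a typical dermatology acquisition: 400 B-scans at a 25 μm
beam increment, 512 A-scans per B-scan, 4 μm axial pitch. The phantom's
`epidermis_thickness` is *defined* as the interval from the entrance
intensity peak to the DEJ valley — exactly the quantity the depth-profile
estimator measures — and the valley intensity is placed exactly on the DEJ
grid point, so noiseless recovery is pixel-exact by construction.

The phantom deliberately omits physical optics: no coherent point-spread
function, refraction, shadowing, motion, or depth-dependent speckle
statistics. Passing phantom tests therefore demonstrates that the *software
chain* is correct and noise-robust under a harsh (SNR ≈ 1) multiplicative
noise model; it does not certify accuracy on any particular scanner, whose
optical blur and motion artefacts add error sources the phantom does not
represent.

Ground-truth Ra is defined on the *discrete sampled grid* rather than the
continuous profile, so recovery tests are grid-exact: `make_plate_phantom()`
rescales a unit triangle-groove profile so that the sampled `mean(|z|)`
equals the requested Ra exactly (6.3 μm reproduces a standard roughness
plate; doubling the target exactly doubles the groove amplitude).

For the skin-like `filtered-noise` profile, the sampled random field is
additionally orthogonalized against the separable quadratic trend space
(lateral quadratic × slice quadratic) before being scaled to its target Ra.
This is an identifiability requirement, not a convenience: a height
component lying inside the trend space is, by definition of the method,
*curvature* — any pipeline that removes curvature must remove it — so a
"ground truth" containing such components could not be recovered by any
curvature-removing estimator. Defining texture in the quotient space makes
the stored truth the unique answer a correct pipeline should reproduce.

## Classical segmentation: two-pass adaptive thresholding

`segment_classical()` locates the surface per column and fills the mask
downward (so every column is a single contiguous skin run — the invariant
all downstream stages rely on). Design choices that matter:

* **Adaptive threshold.** `thr = max(bg_med + k·MAD, bg_med +
  0.25·(peak − bg_med))`, with background statistics from the top image
  rows. Every term scales with intensity, so segmentation is invariant to
  global gain — no empirical per-image threshold.
* **Coarse pass on a smoothed image.** A 3×7 (axial×lateral) boxcar
  averages ~21 speckles, which reduces the intensity coefficient of
  variation about four-fold before the first-exceedance search.
* **Raw-pixel refinement only on quiet backgrounds.** When the background
  coefficient of variation (MAD/median) is below 0.1, the surface is
  refined to the first raw-intensity exceedance within ±2 pixels of the
  coarse estimate — this makes noiseless images pixel-exact. Under fully
  developed speckle the per-pixel SNR is ~1, so single-pixel refinement
  would only re-inject the noise the smoothing removed (on the standard
  plate it tripled the Ra error); it is therefore disabled automatically.
* **Despiking, not smoothing, of the boundary.** Columns deviating from a
  9-column running median by more than 3 pixels are replaced by it;
  everything else is left untouched, so texture peaks are not flattened.

Columns with no supra-threshold pixel are flagged missing and filled later
(linear interpolation in `extract_boundary()`); a B-scan with more than half
its columns missing is rejected as having no reliable boundary.

The neural backend is a compact U-Net (two 3×3 convolution + ReLU layers
per level, 2×2 max pooling, nearest-neighbour upsampling with skip
concatenation, 1×1 output head) trained with Adam on pixel-wise binary
cross-entropy. The default configuration mirrors the common protocol for
OCT boundary segmentation — learning rate 1e-4, batch 8, 100 epochs, 9:1
grouped train/test split — while the encoder is deliberately small
(`base_channels = 4–8`, depth 1–2) so CPU training at desk scale is
practical; the loss value ~0.01 on converged fixtures is treated as a
convergence indicator, not a target. Train/test splits are grouped by
volume, never by B-scan, because adjacent B-scans of one volume are nearly
identical and would leak. Predictions are post-processed exactly like the
classical backend (topmost supra-threshold probability, fill down), so both
backends satisfy the same mask invariants and are interchangeable
downstream. Training at full B-scan size is unnecessary: the network is
fully convolutional, so it can be trained on the surface-containing upper
half of each frame (half the cost per step) and still segment full frames
at prediction time.

## Flattening and the mean-surface reference

`fit_curvature()` is an ordinary least-squares quadratic per B-scan
(centred design matrix for conditioning; exact to machine precision on
quadratic input). `flatten()` subtracts each B-scan's quadratic trend and
then removes the *global* mean of all residuals. Removing the mean globally
— rather than per B-scan — keeps slice-to-slice height structure in the
map, so `|z|` in Ra is measured from the mean surface of the whole region,
which is the ISO mean-line convention.

How each B-scan's quadratic is *estimated* matters more than it first
appears. Fitting every B-scan independently (`method = "per-bscan"`) gives
the trend `3 × n_slices` free coefficients; on textures with long
correlation lengths those coefficients chase the texture and absorb a
realization-dependent 10–40% of it, deflating Ra by a random factor per
volume — enough to visibly erode a cohort-level age trend. The default
(`method = "biquadratic"`) therefore estimates a slice-coherent trend: the
per-slice lateral quadratic fits are themselves projected, per lateral
position, onto a quadratic in the slice index. Anatomical curvature varies
slowly across B-scans, so this sacrifices nothing physically, while texture
can only leak into a handful of global degrees of freedom. Both directions
are commuting orthogonal projections, so flattening is exactly idempotent,
and a curvature that is constant across slices (the phantom model) is
removed exactly by either method. The per-B-scan estimator remains
available; on a single B-scan the two coincide.

Two numerical details:

* Boundary heights are integer-pixel (the mask is the interface contract
  between backends), so a detrended map carries quantization noise of up to
  half an axial pixel. With curvature present, the quantization phase varies
  across the field and largely averages out of Ra.
* The quadratic fit absorbs a small amount of genuine low-frequency texture
  ("fit leakage"), biasing Ra slightly downward; the 5% lateral edge trim in
  `roughness_report()` keeps the fit's worst-leverage columns out of the
  evaluation region. On the 6.3 μm plate phantom with speckle and curvature
  the net pipeline error is about −1.5%, comfortably inside the 2.7%
  validation band, and sweeping the curvature coefficient over
  {0, 1e-6, 3e-6} μm/μm² moves recovered Ra by under 2%.

`Rz` is the literal global peak-to-valley of the evaluation region (not the
ISO five-segment average), which makes it far more outlier-sensitive than
Ra: a single residual boundary spike enters Rz directly. Rz is reported for
completeness; quantitative validation claims are made on Ra.

## Optical metrics

`mean_depth_profile()` shifts every A-scan so depth 0 is its detected
surface, then averages over all columns and slices. Alignment is essential:
without it the entrance peak smears over the surface height range. The
profile's *default* axial smoothing is 1 (none): the cross-sectional average
over ~10⁴ A-scans already suppresses speckle, and a 3-pixel moving average
measurably shifts the asymmetric entrance peak and DEJ valley by 1–2 pixels
(the peak sits on a steep rise and a flat decay, so averaging pulls it
toward the flat side). Extremum *detection* instead runs on an internally
smoothed copy (window 3) with a prominence gate of 2% of the dynamic range,
and each detected extremum is refined to the raw-signal extremum within the
smoothing window — robust to residual micro-extrema, pixel-exact on clean
profiles.

The attenuation fit is OLS on `ln(signal)` vs depth (mm), reported as
`μ = -slope/2` (round-trip single-scattering; the raw slope is kept in the
report for users preferring the one-way convention). The default window
starts 4 pixels below the detected valley — 2 pixels for the junction
itself plus a 2-pixel margin because per-column boundary-detection jitter
smears dark valley values below the nominal DEJ (with the 2-pixel skip
alone, μ was biased by about −0.14 mm⁻¹) — and extends 150 μm down.
Recovery on speckled phantoms is within ~2% across μ ∈ {1, 2, 3} mm⁻¹;
epidermal thickness is recovered within one axial pixel.

## Cohort analysis

`make_cohort()` renders an aging cohort in which ground-truth Ra follows
`baseline + slope·(age − age_min) + N(0, sd)` with ages uniform in the
study range (defaults: 16 subjects, 15–45 years, 8 μm baseline, 0.35
μm/year, 1.5 μm subject noise — a slope chosen so the roughness range over
30 years of aging spans the values typically reported for the back of the
hand). `cohort_analysis()` computes Pearson correlations between age and
each metric, overall and stratified by sex, flagging |r| > 0.6 as strong.
Human-cohort correlation magnitudes from in vivo studies are not
reproducible from synthetic data; what the synthetic cohort validates is
that the *pipeline* preserves a built-in age trend end-to-end (recovered
r ≈ 0.83 at the default conditions, against ≈ 0.90 in the ground truth).

## Problem sizes and determinism

Validation runs use deliberately moderate sizes — plate phantoms of
100×256×512 voxels, cohort volumes of 40×256×256, neural training on
80 B-scans of 128×128 with a 4-channel depth-2 encoder — chosen so the
whole suite replays quickly on a single CPU while every claim above is
still exercised at full fidelity. Every stochastic step (surface fields,
speckle, cohort draws, weight initialization, batch shuffling) is seeded;
identical seeds give bit-identical volumes, masks, reports and trained
weights. Reports serialize floats at fixed precision so reruns are
byte-comparable.

## Known limitations

* Integer-pixel boundary heights floor the measurable roughness at the
  quantization scale; profiles with Ra below ~half an axial pixel are
  reported as quantization noise.
* The per-B-scan quadratic cannot represent curvature varying along the
  slow (slice) axis; a full biquadratic surface fit would be the next step
  for strongly dome-shaped regions.
* Rz inherits boundary outliers by construction (see above).
* The speckle model is spatially white; real OCT speckle has a correlation
  length set by the point-spread function, which would lower the effective
  number of independent speckles per smoothing window.
* The neural backend ships untrained by design; it reaches the same
  accuracy band as the classical backend on phantom data only after
  task-specific training.
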