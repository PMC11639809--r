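---
title: "Motion-based respiratory rate estimation for resting sheep: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-based respiratory rate estimation for resting sheep: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Overview

`ovirr` estimates the respiratory rate (RR) of resting sheep from RGB or
near-infrared (NIR) video without any contact with the animal. The physical
signal is the periodic expansion and contraction of the thorax during the
respiratory cycle, visible as small, coherent displacements of the chest
boundary and of the texture on the fleece. The package implements the full
chain from segmented video to an RR time series, plus a synthetic
breathing-video generator that provides exact ground truth for testing.

The model assumes:

* the animal is **at rest** — locomotion and posture changes produce motion
  that dwarfs breathing and must be excluded upstream (the package's
  coverage accounting quantifies how much footage qualifies);
* a **thorax mask** per animal is available (e.g. from an instance
  segmentation model); masks carry a certainty score, and only detections
  with certainty strictly above 0.75 are processed;
* breathing lies in the **ovine band**: healthy resting sheep breathe at
  roughly 20–30 breaths/min, so the analysis band is fixed at
  0.33–0.67 Hz (19.8–40.2 breaths/min);
* the camera is static; global illumination drift is tolerated because all
  analysis happens on band-passed motion derivatives, not intensities.

## The pipeline

For each retained instance mask:

1. **Mask multiplication.** Every grayscale frame is multiplied by the
   binary thorax mask, zeroing the background so that no tracker can latch
   onto scene clutter.
2. **Contrast enhancement.** Contrast-limited adaptive histogram
   equalisation (CLAHE, 8 × 8 tiles, clip limit 2) spreads the low local
   contrast of fleece texture, which is especially flat in NIR footage.
3. **Feature detection.** FAST segment-test corners (16-pixel Bresenham
   circle, contiguous arc of at least 9, contrast threshold 2 gray levels)
   are detected on the first frame only, restricted to the (slightly
   eroded) mask, spread spatially by keeping the strongest corner per
   4 × 4 pixel cell, and capped at N = 200 points. The low threshold is
   deliberate: fleece texture is faint, and the spatial bucketing prevents
   the cap from being spent on one high-contrast patch.
4. **Tracking.** Each point is followed through the whole clip with
   iterative pyramidal Lucas–Kanade optical flow (21 × 21 window, 3 pyramid
   levels, 30 iterations, convergence threshold 0.01). Points whose solve
   degenerates or that leave the image are dropped permanently; nothing is
   re-seeded, so every surviving trajectory covers every frame.
5. **Differencing.** The horizontal and vertical coordinates of each fully
   valid trajectory are reduced to first differences. This removes the
   absolute position (and any static offset) and leaves the frame-to-frame
   displacement in which breathing lives.
6. **Band-pass filtering.** Every derivative signal is filtered with a
   second-order Butterworth band-pass at 0.33–0.67 Hz applied forward and
   backward (zero phase). Filtering before source separation stops
   out-of-band artefacts (twitches, rumination) from dominating the
   decomposition.
7. **Source separation.** The 2M filtered signals are decomposed with
   principal component analysis. By default the first component is used —
   with a well-masked resting animal the common-mode chest motion is the
   dominant source of variance. A `best_inband` strategy is available that
   scores the first six components by the ratio of in-band spectral peak to
   total power and picks the best, for footage with competing motion.
8. **Spectral RR estimation.** A 10 s window (200 frames at 20 fps, 100 at
   10 fps) slides over the selected component one frame at a time. Each
   window is linearly detrended, zero-padded to 4096 samples, and Fourier
   transformed; the RR is 60 times the frequency of the magnitude-spectrum
   argmax restricted to the band, with ties broken toward the lower
   frequency. Zero-padding to 4096 gives a resolution of about
   0.3 breaths/min at 20 fps; the true quantisation step is therefore
   60·fps/4096 bpm, and differences below it are not meaningful.
9. **Smoothing.** The per-window RR estimates are convolved with a uniform
   moving-average kernel of one window length (10 s).

### Regional analysis

`split_regions()` cuts the mask's bounding box along its longer side into
three equal-width bands: R1 (abdominal end), R2 (middle), R3 (cranial end).
Because the breathing displacement is strongest near the abdomen and fades
toward the head, RR recovered from R1 is expected to be at least as
accurate as from R3; `run_region_comparison()` quantifies this on any clip.

## Numerical choices

* **Detrending** inside each spectral window is done with the closed-form
  least-squares line (centred time axis), applied column-wise to all
  windows at once; the windows are then zero-padded jointly and transformed
  with a single multi-column FFT.
* **Smoothing edges.** A truncated moving average renormalised by the
  actual overlap preserves constants but not the series mean; exact mean
  conservation and the constant fixed point cannot both hold under that
  scheme. The package instead forces the kernel length `round(kernel_s *
  fps)` to be odd (subtracting one if even) and pads the series by
  half-sample mirroring before convolving. The resulting smoothing matrix
  is symmetric and row-stochastic, so a constant series is a fixed point
  *and* the series mean is conserved to numerical precision.
* **Determinism.** The pipeline is free of random numbers (detection,
  tracking, and spectral analysis are deterministic), and the synthetic
  generator derives every stochastic field from its `seed` through an
  isolated RNG scope that restores the caller's random state. Identical
  inputs therefore give byte-identical output CSVs.

## The synthetic generator

`synthetic_spec()` + `generate_breathing_video()` render a speckle-textured
ellipse (the "thorax") over a static textured background. Breathing is
modelled as a radial displacement of the ellipse boundary,
`A(x)·sin(2π f t)`, applied by inverse warping with bilinear sampling; the
amplitude tapers linearly along the long axis from the abdominal end to
`amplitude_gradient` times the full amplitude at the cranial end, which
reproduces the R1 > R2 > R3 ordering of signal strength. Gaussian sensor
noise, linear illumination drift, and 8-bit quantisation are applied last.
The RGB modality renders three channels with slightly different gains and
moderate noise; the NIR modality renders a single lower-contrast channel
with stronger noise. `generate_two_instance_scene()` places two
non-overlapping animals with independent rates in one frame.

The generator emulates: periodic sub-pixel boundary motion with known rate
and amplitude, graded regional signal strength, modality-dependent contrast
and noise, drift, and exact ground truth (`truth.csv`). It does **not**
emulate: posture changes, rumination or twitch artefacts, occlusion between
animals, camera shake, compression artefacts, or segmentation errors —
masks are exact by construction.

Default problem sizes are a package choice made for fast, CPU-only tests:
120 × 160 pixel frames, 30 s clips at 10 or 20 fps. All rate-recovery
properties hold with margin at this scale; nothing in the implementation
depends on it.

## Evaluation toolkit

`agreement()` (mean absolute error in breaths/min and mean relative error
in percent, denominated by the reference), `pearson()` (product-moment
correlation, requiring at least three pairs with nonzero variance),
`bland_altman()` (differences `reference − video`, limits of agreement
`mean ± 1.96·sd` with the sample standard deviation), and `coverage()`
(exact second-level accounting of at-rest versus total footage). Two small
published per-video validation tables ship in `inst/extdata` and are used
by the test suite to reproduce the method's headline statistics; means are
always recomputed at full precision from the rate pairs, which is why a
recomputed headline can differ from a printed, rounded one in the last
digit.

## Limitations

* The package starts from masks; segmentation itself (and its training
  data) is out of scope.
* Video containers are not decoded — frames must be extracted to PNG/TIFF
  directories first.
* RR outside 19.8–40.2 breaths/min is by construction never reported;
  severe tachypnoea would require widening the band.
* The first-component default assumes breathing is the dominant masked
  motion; for restless animals use `component_strategy = "best_inband"`.
* Windows shorter than 10 s are not supported by default because the band's
  lower edge (0.33 Hz) needs several cycles per window to resolve.
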