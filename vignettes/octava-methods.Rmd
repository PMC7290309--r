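---
title: "Denoising and quantifying OCTA en face images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Denoising and quantifying OCTA en face images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Optical coherence tomography angiography (OCTA) renders retinal blood flow
as motion contrast. A single-shot en face image of the superficial capillary
plexus is fast to acquire but heavily degraded: speckle on the flow signal,
a decorrelation noise floor that fills avascular regions (most visibly the
foveal avascular zone, FAZ), and flow-signal dropout that fragments
capillaries. The classical remedy is to scan the same field many times,
register the repeats, and average them — which costs an order of magnitude
more chair time. `octava` implements the fast alternative: a convolutional
encoder–decoder trained to map a single shot directly to its multi-frame
average, together with the complete measurement suite needed to judge
whether such a denoiser helps or distorts quantitative vascular metrics.

All pixel rasters are 8-bit, row-major, origin top-left, `(row, col)`
indexed, with pixel centers on integer coordinates. The default field is
232 × 232 px covering 3 × 3 mm (0.01293 mm/px).

## Synthetic eyes

Because real patient scans cannot ship with a package, every stage is
exercised on simulated eyes with known ground truth:

* **Vasculature** (`generate_vessel_truth`): stochastic branching trees grow
  inward from the field border toward the FAZ boundary, with small random
  heading changes per 2-px step, side branches (child radius 0.7× the
  parent), and radii tapering 0.5% per step from ~3 px trunks down to a
  0.8 px floor. Centerlines are steered away from the FAZ disc (default
  radius 0.25 mm, a typical adult FAZ) so it stays capillary-free.
* **Clean render** (`render_clean`): anti-aliased discs stamped along each
  centerline (peak intensity 0.85), over a faint blurred-noise capillary-bed
  texture (level 0.15) that stands in for capillaries below the grid's
  resolving power; the FAZ interior is exactly zero.
* **Single shots** (`simulate_single_shot`): per-segment dropout gaps
  (geometric run lengths, probability 0.2 per segment), multiplicative
  mean-one gamma speckle (shape 6), additive folded-normal background noise
  (scale 0.20 × 255), then optional focal artifacts — a circular shadow
  attenuating the signal (emulating focal signal attenuation, under which
  denoisers are prone to erasing real capillaries) and a bright motion line
  on one row. Frames get independent integer translations bounded by
  ±3 px; frame 1 is the "original" by convention and is never shifted.

The noise defaults were chosen once so that the simulated cohort shows the
qualitative single-shot pathology the method addresses — a fragmented,
noisy original whose thresholded mask neither starves (vessel dropout) nor
floods (noise) relative to the averaged image. With `noise_off()` the whole
simulator is an identity pipeline, which the tests exploit. The simulator
intentionally does **not** model physically accurate OCT speckle
statistics, axial structure, or projection artifacts from deeper plexuses;
conclusions from passing tests are about the pipeline's mechanics and the
relative behavior of the three image classes, not about clinical
performance.

## Averaging as teacher

`register_frames` does translation-only registration: exhaustive normalized
cross-correlation against frame 1 over integer shifts within `max_shift`
(default 10 px). This matches the simulator's motion model; subpixel or
deformable registration is out of scope. Frames whose peak correlation
falls below 0.2 are excluded, modeling repeats lost to poor fixation.
`average_frames` takes the per-pixel mean over the frames covering each
pixel after re-alignment (no cropping), so the averaged image keeps the
input geometry — a requirement for pixelwise PSNR later.

## The denoiser

The network is a standard U-Net-shaped encoder–decoder: `depth = 3`
poolings (2 × 2 mean), channel widths doubling per scale, two 3 × 3
convolutions with leaky-ReLU (slope 0.1) per scale, nearest-neighbor
upsampling, skip connections by concatenation, and a linear 3 × 3 head
regressing intensities on the [0, 1] scale. Training pairs are 64-px tiles
cut at stride 32 from (single-shot, registered-average) image pairs of the
same eye — never across eyes — and the loss is pixelwise L1 by default
(robust against speckle outliers; L2 is available). Optimization is Adam
(learning rate 2e-3, batch 8, 250 steps by default), fully seeded:
initialization and batch sampling derive from `config$seed`, so a rerun
reproduces the loss history.

Width default: `base_channels = 8`. With the package's pure-R/BLAS
convolution engine this trains on a 20-eye cohort in roughly 3 minutes on
one CPU core; doubling the width quadruples the arithmetic and pushes
training well past desk scale without changing any tested behavior, so the
narrower net is the default. Inference tiles the full image at stride
`patch_px / 2` with uniform overlap averaging, then clips and quantizes to
8 bits.

The engine computes convolutions as im2col gathers (a small compiled
routine) followed by BLAS matrix products; the backward pass reuses the
cached gathers and mirrors the offsets for the input gradient. Every
gradient is verified against numeric differentiation in the test suite.
The network regresses teacher intensities rather than classifying pixels:
the measurement chain downstream (thresholding, skeletonization) needs a
grayscale image, and regression-to-average is the natural formalization of
learning from an averaged teacher.

## Quality metrics

* **CNR** uses one background disc inside the FAZ and four foreground discs
  near the corners, all 20 px in diameter (~314 px² continuous area), with
  `CNR = (f − b) / sqrt(δf² + δb²)`. The four foreground discs are pooled
  into one pixel set; discs rasterize as pixels whose centers fall within
  the radius; standard deviations use the population convention. The FAZ
  center defaults to the image center (fovea-centered scans) and is
  overridable for real images. The same ROI set is placed once per eye and
  reused across the three images, mirroring ROI-manager practice.
* **PSNR** is `10 log10(255²/MSE)` against the averaged image as reference;
  identical images give an `Inf` sentinel, never an error.

## Vascular metrics

`binarize` applies a 3 × 3 median prefilter and by default Otsu's global
threshold; the device software that inspired this chain is unpublished, so
the method is configurable (`mean_local`, `fixed`) and all direction claims
in the tests hold under the defaults. Metrics are conventionally computed
on a 500 × 500 nearest-neighbor resample (the export grid of the device
chain; box counting then also runs at that scale), with `mm_per_pixel`
rescaled accordingly.

* **VD**: vessel-pixel fraction of the mask.
* **Skeleton**: Zhang–Suen two-subiteration thinning (no installed package
  provides thinning), plus a cleanup pass so no 2 × 2 block survives.
* **VLD**: skeleton length per field area. Length uses 8-neighbor steps —
  1 px orthogonal, √2 px diagonal, with a diagonal step skipped when an
  orthogonal corner pixel already carries the path, and isolated pixels
  counting 1 px. This is unbiased for diagonal vessels, unlike raw pixel
  counts. The denominator is the full field area.
* **VDI**: mask area / skeleton length (same length rule), a mean-caliber
  proxy in pixels.
* **FD**: box counting on the skeleton with box sides 2, 4, 8, … up to a
  quarter of the smaller dimension, a single grid anchored at the origin
  (deterministic, matching common ImageJ practice), least-squares slope of
  log N(s) vs log(1/s), clamped to [0, 2] with a warning. An empty skeleton
  gives 0 with a warning; fewer than three usable box sizes is an error.

## The cohort experiment

`run_experiment` reproduces the three-arm comparison at desk scale:
20 training eyes and 10 held-out test eyes, 10 frames each (the package's
default problem size throughout the tests and the acceptance script). Per
test eye it emits the original (frame 1), averaged, and denoised images and
all metrics; `compare_groups` then reports mean ± SD per group, one-way
ANOVA with Tukey HSD pairwise adjusted p-values for VD/VLD/VDI/FD/CNR, and
a paired t-test for PSNR (original vs denoised only — the averaged image is
the PSNR reference and has no PSNR of its own). Keeping the t-test/ANOVA
split, instead of one uniform framework, mirrors how such three-arm studies
are conventionally reported.

On this synthetic cohort the expected directions — denoised above original
on CNR and PSNR, below it on VLD and FD, above it on VDI, and all three VD
means close together — are asserted by the acceptance tests; the magnitudes
depend on the simulator and are not claims about any clinical dataset.

## Numerical conventions and edge cases

* 16-bit rasters are rescaled by their maximum on read (export depth of
  real devices varies; the max rule is scale-free).
* A constant image binarizes to an empty mask with a warning; CNR of a
  constant image is 0; zero spread with unequal ROI means is an error.
* An empty skeleton makes VDI an error (undefined ratio) but FD a warned 0.
* All randomness flows through integer seeds below 2³¹; child streams are
  derived with a fixed LCG so seeds never collide across stages.

## Known limitations

* The simulator's noise is a stylized stand-in; no claim of OCT physics.
* Registration is integer-translation only; rotation or warping in real
  repeats would need an external registration step first.
* The denoiser trains at desk scale (tens of eyes, hundreds of steps); it
  demonstrates the method, not a clinically tuned model.
* Artifact phenomena (shadow, motion line) are simulated as inputs;
  automatic artifact detection is out of scope.
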