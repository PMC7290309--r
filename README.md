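# octava

Denoising and quantitative analysis of OCT angiography (OCTA) en face
images in R.

Single-shot OCTA images of the retinal superficial capillary plexus are
fast to acquire but noisy: speckle roughens vessels, a decorrelation noise
floor fills the foveal avascular zone (FAZ), and flow dropout fragments
capillaries. The classical fix — scanning the same field ten times,
registering and averaging — is slow in the chair. `octava` implements the
fast alternative and the measurements needed to judge it:

* **Multi-frame enhancement**: translation registration by normalized
  cross-correlation and per-pixel averaging of repeated frames, producing
  the reference ("teacher") image.
* **Learned denoising**: a U-Net-style convolutional encoder–decoder
  trained on (single-shot tile → averaged tile) pairs from the same eye,
  applied to whole images by overlapped tiling. The network, its
  backpropagation, and its Adam optimizer are implemented in the package
  (R + BLAS, with a small compiled im2col kernel) and are fully seeded.
* **Image-quality metrics**: contrast-to-noise ratio
  `CNR = (f − b)/√(δf² + δb²)` with one FAZ background disc and four corner
  foreground discs (diameter 20 px), and peak signal-to-noise ratio
  `PSNR = 10·log10(255²/MSE)` against the averaged reference.
* **Vascular metrics** on binarized (median prefilter + Otsu, optional
  500 × 500 export grid) and skeletonized (Zhang–Suen thinning) images:
  vessel density (VD), vessel length density (VLD, mm⁻¹), vessel diameter
  index (VDI), and box-counting fractal dimension (FD ∈ [0, 2]).
* **A synthetic-eye simulator** (branching vasculature with a
  capillary-free FAZ, gamma speckle, background noise floor, dropout,
  inter-frame jitter, optional shadow and motion-line artifacts) so the
  entire pipeline runs and is tested without patient data.
* **A cohort experiment driver** producing original/averaged/denoised
  triplets and the group statistics: ANOVA + Tukey HSD for VD/VLD/VDI/FD/
  CNR, paired t-test for PSNR.

## Worked example

```r
library(octava)

# simulate one eye: 10 repeated noisy frames of the same vasculature
stack <- simulate_eye(n_frames = 10, seed = 3)

# register and average the repeats; frame 1 is the "original" single shot
reg <- register_frames(stack, max_shift = 5)
avg <- average_frames(stack, reg)
orig <- stack$frames[[1]]

cnr(orig)$cnr_value       # 0.721
cnr(avg)$cnr_value        # 1.115
psnr(orig, avg)$psnr_db   # 16.72 dB

mask <- binarize(orig, resample_to_500 = TRUE)
skel <- skeletonize_mask(mask)
vessel_density(mask)              # 0.208
vessel_length_density(skel)       # 10.88 mm^-1
vessel_diameter_index(mask, skel) # 3.19 px
fractal_dimension(skel)           # 1.395
```

The single shot scores a markedly lower CNR than the 10-frame average
(background noise in the FAZ inflates `δb`), and its PSNR against the
average quantifies how far one frame sits from the teacher. The full
three-arm comparison — train a denoiser on 20 simulated eyes, score 10
held-out eyes — is one call:

```r
res <- run_experiment(experiment_config(seed = 1))
res$report
#  cnr      original 0.6816 ... denoised 1.246  (Tukey p = 0.019)
#  psnr_db  original 16.76  ... denoised 20.26  (paired t p = 1.5e-09)
#  vld      original 10.48  ... denoised 7.84   (lower after denoising)
#  vdi      original 3.281  ... denoised 4.665  (higher after denoising)
#  fd       original 1.378  ... denoised 1.325  (lower after denoising)
#  vd       0.206 / 0.230 / 0.219                (no significant difference)
```

Denoising raises contrast and similarity-to-average, prunes noise-driven
skeleton fragments (lower VLD and FD), thickens and smooths vessel
profiles (higher VDI), and leaves overall vessel density statistically
flat — the signature pattern of averaging-teacher denoisers.

A command-line front end wrapping these functions is installed at
`inst/cli/octava.R` (subcommands `simulate`, `average`, `train`, `denoise`,
`qc`, `vessels`, `experiment`).

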