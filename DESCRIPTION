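Package: octava
Title: Denoising and Quantitative Analysis of OCT Angiography En Face Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for enhancing and quantifying en face optical coherence
    tomography angiography (OCTA) images. Implements multi-frame registration
    and averaging of repeated acquisitions, a convolutional encoder-decoder
    denoiser trained with single-shot images as input and registered averaged
    images as the teacher, objective image-quality metrics (contrast-to-noise
    ratio with an FAZ/corner ROI scheme, peak signal-to-noise ratio against
    the averaged reference), and microvascular metrics computed from binarized
    and skeletonized images (vessel density, vessel length density, vessel
    diameter index, and box-counting fractal dimension). A synthetic angiogram
    simulator with known ground-truth vasculature makes the full pipeline
    testable end to end, and an experiment driver reproduces the
    original/averaged/denoised group comparisons with ANOVA, Tukey HSD, and
    paired t-tests.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    stats,
    utils,
    EBImage,
    Rcpp
LinkingTo: Rcpp
Suggests:
    tiff,
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
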