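# Small fixtures built in code, shared across test files.

# A flat image with a single bright horizontal bar.
bar_image <- function(h = 64, w = 64, rows = 30:33, cols = 10:49,
                      value = 200L, bg = 0L) {
  px <- matrix(bg, h, w)
  px[rows, cols] <- value
  enface_image(px)
}

# A vessel mask built directly (no thresholding), for metric arithmetic.
mask_from_matrix <- function(m, mm_per_pixel = 3 / ncol(m)) {
  structure(list(mask = m, mm_per_pixel = mm_per_pixel,
                 source_label = "original"),
            class = "vessel_mask")
}

skeleton_from_matrix <- function(m, mm_per_pixel = 3 / ncol(m)) {
  structure(list(mask = m, mm_per_pixel = mm_per_pixel),
            class = "skeleton_mask")
}

# One small noiseless synthetic eye reused across files (cached per session).
small_clean_eye <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      truth <- generate_vessel_truth(field_px = 96L, mm_per_pixel = 3 / 96,
                                     n_trees = 4L, seed = 99L)
      cache <<- render_clean(truth)
    }
    cache
  }
})
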