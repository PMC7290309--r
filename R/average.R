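#' Register repeated frames to the first frame
#'
#' Translation-only registration: for each frame the integer shift within
#' `max_shift` that maximizes the normalized cross-correlation with frame 1
#' over the overlap region. Frames whose peak correlation falls below
#' `exclude_below` are flagged excluded (modeling frames that fail to
#' register, e.g. from poor fixation); the reference frame is never excluded.
#'
#' The reported offset is the shift that re-aligns a frame onto frame 1:
#' a frame whose content moved by `(3, -2)` gets offset `(-3, 2)`.
#'
#' @param stack a [simulate_eye()] `frame_stack`, or a plain list of
#'   [enface_image()] frames.
#' @param max_shift search bound in pixels (default 10).
#' @param exclude_below peak-correlation exclusion threshold (default 0.2).
#' @return An object of class `registration_result`: `offsets` (n x 2 integer
#'   matrix), `peak_correlation` (numeric), `excluded_frames` (integer
#'   indices).
#' @export
register_frames <- function(stack, max_shift = 10L, exclude_below = 0.2) {
  frames <- if (inherits(stack, "frame_stack")) stack$frames else stack
  if (length(frames) < 2) stopf("registration needs at least 2 frames")
  dims <- vapply(frames, function(f) dim(f$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stopf("all frames must have identical dimensions")
  }
  ref <- frames[[1]]$pixels
  n <- length(frames)
  offsets <- matrix(0L, n, 2)
  peaks <- numeric(n)
  peaks[1] <- 1
  shifts <- seq.int(-max_shift, max_shift)
  h <- nrow(ref); w <- ncol(ref)
  for (i in seq_len(n)[-1]) {
    img <- frames[[i]]$pixels
    best <- -Inf; best_off <- c(0L, 0L)
    for (dr in shifts) {
      rr_ref <- max(1, 1 + dr):min(h, h + dr)
      rr_img <- rr_ref - dr
      for (dc in shifts) {
        cc_ref <- max(1, 1 + dc):min(w, w + dc)
        cc_img <- cc_ref - dc
        a <- ref[rr_ref, cc_ref]
        b <- img[rr_img, cc_img]
        r <- suppressWarnings(stats::cor(as.vector(a), as.vector(b)))
        if (is.na(r)) r <- 0
        if (r > best) { best <- r; best_off <- c(dr, dc) }
      }
    }
    offsets[i, ] <- as.integer(best_off)
    peaks[i] <- best
  }
  excluded <- which(peaks < exclude_below)
  excluded <- setdiff(excluded, 1L)
  if (length(excluded) == n - 1 && peaks[1] < exclude_below) {
    stopf("registration failed: all frames excluded")
  }
  structure(list(offsets = offsets, peak_correlation = peaks,
                 excluded_frames = as.integer(excluded)),
            class = "registration_result")
}

#' Average registered frames into the multi-frame reference image
#'
#' Re-aligns each non-excluded frame by its registration offset and takes the
#' per-pixel arithmetic mean over the frames that cover that pixel (frames
#' shifted off the border contribute nothing there), so the output keeps the
#' input dimensions. The result is rounded to 8 bits.
#'
#' @param stack a `frame_stack` or list of [enface_image()] frames.
#' @param reg a [register_frames()] result; identity registration is assumed
#'   when omitted.
#' @return An [enface_image()] with label `"averaged"`.
#' @export
average_frames <- function(stack, reg = NULL) {
  frames <- if (inherits(stack, "frame_stack")) stack$frames else stack
  n <- length(frames)
  if (is.null(reg)) {
    reg <- structure(list(offsets = matrix(0L, n, 2),
                          peak_correlation = rep(1, n),
                          excluded_frames = integer(0)),
                     class = "registration_result")
  }
  keep <- setdiff(seq_len(n), reg$excluded_frames)
  if (length(keep) < 1) stopf("no frames left to average")
  h <- nrow(frames[[1]]$pixels); w <- ncol(frames[[1]]$pixels)
  acc <- matrix(0, h, w)
  cnt <- matrix(0, h, w)
  for (i in keep) {
    off <- reg$offsets[i, ]
    acc <- acc + shift_matrix(frames[[i]]$pixels, off)
    cnt <- cnt + shift_matrix(matrix(1, h, w), off)
  }
  avg <- acc / pmax(cnt, 1)
  enface_image(matrix(as.integer(round(clamp(avg, 0, 255))), h, w),
               mm_per_pixel = frames[[1]]$mm_per_pixel, label = "averaged",
               seed = frames[[1]]$seed, provenance = "average_frames")
}
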