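#' Place the CNR regions of interest: FAZ background plus four corner discs
#'
#' One circular background ROI centered in the foveal avascular zone and four
#' circular foreground ROIs near the image corners, all of the same diameter
#' (default 20 px, continuous area about 314 px^2). Discs are rasterized as
#' the pixels whose centers lie within the radius of the ROI center (ties
#' included) — the one disc convention used throughout the package.
#'
#' @param image an [enface_image()].
#' @param faz_center background ROI center `(row, col)`; defaults to the
#'   image center (the scan is fovea-centered).
#' @param diameter_px ROI diameter in pixels (default 20).
#' @param corner_inset_px distance from each image edge to the near edge of a
#'   corner ROI (default 10).
#' @return An object of class `roi_set`: `background` and `foreground`
#'   (lists of `list(center, diameter_px, pixels)` where `pixels` is an
#'   n x 2 matrix of (row, col)).
#' @export
place_cnr_rois <- function(image, faz_center = NULL, diameter_px = 20L,
                           corner_inset_px = 10L) {
  stopifnot(inherits(image, "enface_image"))
  h <- nrow(image$pixels); w <- ncol(image$pixels)
  r <- diameter_px / 2
  if (diameter_px + 2 * corner_inset_px > min(h, w)) {
    stopf("ROI diameter %d with corner inset %d does not fit in a %d x %d image",
          diameter_px, corner_inset_px, h, w)
  }
  if (is.null(faz_center)) faz_center <- round(c((h + 1) / 2, (w + 1) / 2))
  disc <- function(center) {
    r0 <- ceiling(center[1] - r); r1 <- floor(center[1] + r)
    c0 <- ceiling(center[2] - r); c1 <- floor(center[2] + r)
    if (r0 < 1 || c0 < 1 || r1 > h || c1 > w) {
      stopf("ROI at (%.1f, %.1f) extends outside the image", center[1], center[2])
    }
    rr <- r0:r1; cc <- c0:c1
    d2 <- outer((rr - center[1])^2, (cc - center[2])^2, "+")
    idx <- which(d2 <= r^2 + 1e-9, arr.ind = TRUE)
    cbind(row = rr[idx[, 1]], col = cc[idx[, 2]])
  }
  edge <- corner_inset_px + r
  corners <- list(c(edge, edge), c(edge, w + 1 - edge),
                  c(h + 1 - edge, edge), c(h + 1 - edge, w + 1 - edge))
  rois <- structure(list(
    background = list(center = faz_center, diameter_px = diameter_px,
                      pixels = disc(faz_center)),
    foreground = lapply(corners, function(ct)
      list(center = ct, diameter_px = diameter_px, pixels = disc(ct)))),
    class = "roi_set")
  bg_keys <- paste(rois$background$pixels[, 1], rois$background$pixels[, 2])
  for (fg in rois$foreground) {
    if (any(paste(fg$pixels[, 1], fg$pixels[, 2]) %in% bg_keys)) {
      stopf("background and foreground ROIs overlap")
    }
  }
  rois
}

roi_values <- function(image, roi) {
  image$pixels[cbind(roi$pixels[, 1], roi$pixels[, 2])]
}

#' Contrast-to-noise ratio between vessel foreground and FAZ background
#'
#' `CNR = (f - b) / sqrt(delta_f^2 + delta_b^2)` where `f`, `delta_f` are the
#' mean and standard deviation of the pooled pixels of the four foreground
#' (corner) ROIs and `b`, `delta_b` those of the background (FAZ) ROI.
#' Standard deviations use the population convention (denominator n).
#'
#' @param image an [enface_image()].
#' @param rois a [place_cnr_rois()] result (defaults placed on `image`).
#' @return A list with `stats` (`f`, `b`, `delta_f`, `delta_b`) and
#'   `cnr_value`.
#' @export
cnr <- function(image, rois = place_cnr_rois(image)) {
  fg <- unlist(lapply(rois$foreground, function(roi) roi_values(image, roi)))
  bg <- roi_values(image, rois$background)
  sd_pop <- function(x) sqrt(mean((x - mean(x))^2))
  f <- mean(fg); b <- mean(bg)
  df <- sd_pop(fg); db <- sd_pop(bg)
  denom <- sqrt(df^2 + db^2)
  if (denom == 0) {
    if (f != b) stopf("degenerate ROI statistics: zero spread with unequal means")
    value <- 0
  } else {
    value <- (f - b) / denom
  }
  list(stats = list(f = f, b = b, delta_f = df, delta_b = db),
       cnr_value = value)
}

#' Peak signal-to-noise ratio against a reference image
#'
#' `PSNR = 10 log10(255^2 / MSE)` in dB, where MSE is the mean squared pixel
#' difference and 255 is the peak of the 8-bit range. Identical images give
#' `psnr_db = Inf` (a documented sentinel, not an error).
#'
#' @param sample an [enface_image()] to score.
#' @param reference the reference [enface_image()] (here the averaged image).
#' @return A list with `mse`, `max_i` (255) and `psnr_db`.
#' @export
psnr <- function(sample, reference) {
  stopifnot(inherits(sample, "enface_image"), inherits(reference, "enface_image"))
  if (!identical(dim(sample$pixels), dim(reference$pixels))) {
    stopf("sample and reference dimensions differ")
  }
  mse <- mean((as.numeric(sample$pixels) - as.numeric(reference$pixels))^2)
  list(mse = mse, max_i = 255,
       psnr_db = if (mse == 0) Inf else 10 * log10(255^2 / mse))
}
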