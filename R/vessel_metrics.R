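#' Binarize an en face image into a vessel mask
#'
#' A 3x3 median prefilter suppresses salt noise, then a threshold classifies
#' vessel pixels. The default is Otsu's global histogram threshold;
#' `"mean_local"` thresholds against a local box mean, `"fixed"` uses an
#' explicit cut. With `resample_to_500 = TRUE` the image is first resampled
#' (nearest neighbor) to the 500 x 500 export grid on which the
#' morphological metrics are conventionally computed; the physical scale is
#' adjusted accordingly.
#'
#' @param image an [enface_image()].
#' @param method `"otsu"`, `"mean_local"`, or `"fixed"`.
#' @param threshold intensity cut in `[0, 255]` for `method = "fixed"`.
#' @param resample_to_500 resample to 500 x 500 before thresholding.
#' @return An object of class `vessel_mask`: logical matrix `mask`,
#'   `mm_per_pixel`, `source_label`.
#' @export
binarize <- function(image, method = c("otsu", "mean_local", "fixed"),
                     threshold = NULL, resample_to_500 = FALSE) {
  stopifnot(inherits(image, "enface_image"))
  method <- match.arg(method)
  px <- image$pixels
  mmpp <- image$mm_per_pixel
  if (resample_to_500) {
    h <- nrow(px); w <- ncol(px)
    ri <- pmin(h, pmax(1, round((seq_len(500) - 0.5) * h / 500 + 0.5)))
    ci <- pmin(w, pmax(1, round((seq_len(500) - 0.5) * w / 500 + 0.5)))
    mmpp <- mmpp * h / 500
    px <- px[ri, ci]
  }
  x01 <- px / 255
  x01 <- as.matrix(EBImage::medianFilter(EBImage::Image(x01), size = 1))
  if (max(x01) == min(x01)) {
    warning("constant image: threshold undefined, returning empty mask")
    mask <- matrix(FALSE, nrow(px), ncol(px))
  } else {
    mask <- switch(method,
      otsu = {
        th <- EBImage::otsu(EBImage::Image(x01), range = c(0, 1), levels = 256)
        x01 > th
      },
      mean_local = {
        k <- matrix(1 / 225, 15, 15)
        mu <- as.matrix(EBImage::filter2(EBImage::Image(x01), k))
        x01 > mu + 0.02
      },
      fixed = {
        if (is.null(threshold)) stopf("method 'fixed' requires `threshold`")
        x01 > threshold / 255
      })
  }
  structure(list(mask = matrix(as.logical(mask), nrow(px), ncol(px)),
                 mm_per_pixel = mmpp, source_label = image$label),
            class = "vessel_mask")
}

# Zhang-Suen neighborhood, clockwise from north:
# p2=N, p3=NE, p4=E, p5=SE, p6=S, p7=SW, p8=W, p9=NW
zs_neighbors <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(0L, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  list(p2 = pad[1:h, 2:(w + 1)],       p3 = pad[1:h, 3:(w + 2)],
       p4 = pad[2:(h + 1), 3:(w + 2)], p5 = pad[3:(h + 2), 3:(w + 2)],
       p6 = pad[3:(h + 2), 2:(w + 1)], p7 = pad[3:(h + 2), 1:w],
       p8 = pad[2:(h + 1), 1:w],       p9 = pad[1:h, 1:w])
}

#' Skeletonize a vessel mask to one-pixel-wide centerlines
#'
#' Topology-preserving morphological thinning (Zhang-Suen two-subiteration
#' scheme, with a final pass removing pixels that only thicken 2x2 blocks).
#' The skeleton is always a subset of the mask; isolated pixels survive.
#'
#' @param mask a [binarize()] result.
#' @return An object of class `skeleton_mask` with fields `mask` (logical
#'   matrix) and `mm_per_pixel`.
#' @export
skeletonize_mask <- function(mask) {
  stopifnot(inherits(mask, "vessel_mask"))
  m <- mask$mask * 1L
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      nb <- zs_neighbors(m)
      bsum <- nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9
      seqs <- list(nb$p2, nb$p3, nb$p4, nb$p5, nb$p6, nb$p7, nb$p8, nb$p9, nb$p2)
      a <- 0L
      for (i in 1:8) a <- a + (seqs[[i]] == 0L & seqs[[i + 1]] == 1L)
      if (sub == 1) {
        c1 <- nb$p2 * nb$p4 * nb$p6
        c2 <- nb$p4 * nb$p6 * nb$p8
      } else {
        c1 <- nb$p2 * nb$p4 * nb$p8
        c2 <- nb$p2 * nb$p6 * nb$p8
      }
      del <- m == 1L & bsum >= 2 & bsum <= 6 & a == 1L & c1 == 0L & c2 == 0L
      if (any(del)) { m[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  # staircase cleanup: remove a pixel of any remaining fully-set 2x2 block
  repeat {
    h <- nrow(m); w <- ncol(m)
    blk <- m[1:(h - 1), 1:(w - 1)] & m[2:h, 1:(w - 1)] &
      m[1:(h - 1), 2:w] & m[2:h, 2:w]
    if (!any(blk)) break
    idx <- which(blk, arr.ind = TRUE)[1, ]
    m[idx[1] + 1, idx[2] + 1] <- 0L
  }
  structure(list(mask = m == 1L, mm_per_pixel = mask$mm_per_pixel),
            class = "skeleton_mask")
}

#' Vessel density: fraction of the field classified as vessel
#' @param mask a [binarize()] result.
#' @return Vessel-pixel count divided by total pixel count, in `[0, 1]`.
#' @export
vessel_density <- function(mask) {
  stopifnot(inherits(mask, "vessel_mask"))
  mean(mask$mask)
}

# Centerline length in pixel units under the 8-neighbor step rule: 1 per
# orthogonal adjacency, sqrt(2) per diagonal adjacency not shortcut by an
# orthogonal corner pixel; isolated pixels count one pixel length.
skeleton_length_px <- function(m) {
  h <- nrow(m); w <- ncol(m)
  right <- m[, 1:(w - 1)] & m[, 2:w]
  down <- m[1:(h - 1), ] & m[2:h, ]
  n_orth <- sum(right) + sum(down)
  dr <- m[1:(h - 1), 1:(w - 1)] & m[2:h, 2:w] &
    !m[1:(h - 1), 2:w] & !m[2:h, 1:(w - 1)]
  dl <- m[1:(h - 1), 2:w] & m[2:h, 1:(w - 1)] &
    !m[1:(h - 1), 1:(w - 1)] & !m[2:h, 2:w]
  n_diag <- sum(dr) + sum(dl)
  nb <- zs_neighbors(m * 1L)
  any_nb <- nb$p2 + nb$p3 + nb$p4 + nb$p5 + nb$p6 + nb$p7 + nb$p8 + nb$p9
  isolated <- sum(m & any_nb == 0L)
  n_orth + sqrt(2) * n_diag + isolated
}

#' Vessel length density: centerline length per unit field area
#'
#' Total skeleton length (8-neighbor step rule: orthogonal steps count one
#' pixel, diagonal steps `sqrt(2)` pixels, isolated pixels one pixel)
#' converted to mm, divided by the field area in mm^2.
#'
#' @param skeleton a [skeletonize_mask()] result.
#' @return Length density in 1/mm.
#' @export
vessel_length_density <- function(skeleton) {
  stopifnot(inherits(skeleton, "skeleton_mask"))
  m <- skeleton$mask
  len_mm <- skeleton_length_px(m) * skeleton$mm_per_pixel
  area_mm2 <- nrow(m) * ncol(m) * skeleton$mm_per_pixel^2
  len_mm / area_mm2
}

#' Vessel diameter index: mean vessel caliber
#'
#' Total vessel area of the binarized mask divided by total centerline length
#' of the skeleton (same length rule as [vessel_length_density()]), in
#' pixels; multiply by `mm_per_pixel * 1000` for micrometers.
#'
#' @param mask a [binarize()] result.
#' @param skeleton the matching [skeletonize_mask()] result.
#' @return Mean caliber in pixels.
#' @export
vessel_diameter_index <- function(mask, skeleton) {
  stopifnot(inherits(mask, "vessel_mask"), inherits(skeleton, "skeleton_mask"))
  len <- skeleton_length_px(skeleton$mask)
  if (len == 0) stopf("VDI undefined: empty skeleton")
  sum(mask$mask) / len
}

#' Box-counting fractal dimension of a skeleton
#'
#' Boxes of side `s = 2, 4, 8, ...` up to a quarter of the smaller image
#' dimension, on a single fixed grid anchored at the origin; `N(s)` counts
#' boxes containing at least one skeleton pixel. FD is the least-squares
#' slope of `log N(s)` versus `log(1/s)`, clamped to `[0, 2]` (with a
#' warning if clamping occurs). An empty skeleton returns 0 with a warning.
#'
#' @param skeleton a [skeletonize_mask()] result.
#' @return Fractal dimension in `[0, 2]`.
#' @export
fractal_dimension <- function(skeleton) {
  stopifnot(inherits(skeleton, "skeleton_mask"))
  m <- skeleton$mask
  if (!any(m)) {
    warning("empty skeleton: fractal dimension undefined, returning 0")
    return(0)
  }
  smax <- min(dim(m)) / 4
  sizes <- 2^(1:30)
  sizes <- sizes[sizes <= smax]
  if (length(sizes) < 3) stopf("image too small for box counting (need >= 3 box sizes)")
  pix <- which(m, arr.ind = TRUE)
  counts <- vapply(sizes, function(s) {
    boxes <- (pix[, 1] - 1) %/% s + 1e5 * ((pix[, 2] - 1) %/% s)
    length(unique(boxes))
  }, 0)
  fit <- stats::lm.fit(cbind(1, log(1 / sizes)), log(counts))
  fd <- unname(fit$coefficients[2])
  if (fd < -1e-9 || fd > 2 + 1e-9) {
    warning(sprintf("fractal dimension %.3f outside [0, 2]; clamped", fd))
  }
  clamp(fd, 0, 2)
}
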