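#' Noise and artifact parameters for the single-shot simulator
#'
#' Describes the degradations applied to a clean render to emulate one
#' single-shot acquisition: multiplicative speckle on the flow signal,
#' an additive background noise floor that dominates avascular areas,
#' per-segment flow-decorrelation dropout gaps, bounded inter-frame
#' translation, and two optional focal artifacts (a circular
#' signal-attenuation shadow and a bright motion line on one row).
#'
#' @param speckle_shape positive shape of the mean-one gamma speckle
#'   multiplier; larger values mean less speckle. `Inf` disables speckle.
#' @param background_level additive noise floor in `[0, 1]` (fraction of the
#'   8-bit range; folded-normal scale is `background_level * 255`).
#' @param dropout_prob per-segment probability in `[0, 1]` of a local
#'   decorrelation gap along the centerline.
#' @param jitter_max_px nonnegative integer bound on per-frame translation.
#' @param shadow optional list `list(center = c(row, col), radius_px,
#'   attenuation)` with attenuation in `[0, 1]` (multiplier inside the disc).
#' @param motion_line optional list `list(row, gain)`; intensities on that
#'   row are multiplied by `gain`.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(speckle_shape = 6, background_level = 0.20,
                         dropout_prob = 0.2, jitter_max_px = 3L,
                         shadow = NULL, motion_line = NULL) {
  stopifnot(speckle_shape > 0,
            background_level >= 0, background_level <= 1,
            dropout_prob >= 0, dropout_prob <= 1,
            is_count(jitter_max_px))
  if (!is.null(shadow)) {
    stopifnot(length(shadow$center) == 2, shadow$radius_px >= 0,
              shadow$attenuation >= 0, shadow$attenuation <= 1)
  }
  if (!is.null(motion_line)) stopifnot(motion_line$row >= 1, motion_line$gain >= 0)
  structure(list(speckle_shape = speckle_shape,
                 background_level = background_level,
                 dropout_prob = dropout_prob,
                 jitter_max_px = as.integer(jitter_max_px),
                 shadow = shadow, motion_line = motion_line),
            class = "noise_params")
}

#' Noise-free parameter set (identity simulator)
#' @return A `noise_params` with every degradation disabled.
#' @export
noise_off <- function() {
  noise_params(speckle_shape = Inf, background_level = 0, dropout_prob = 0,
               jitter_max_px = 0L)
}

#' Generate ground-truth vasculature for a synthetic eye
#'
#' Grows stochastic branching vessel trees inward from the field edges toward
#' the boundary of a central foveal avascular zone (FAZ). Each tree is a set
#' of centerline polylines with a per-point radius profile that tapers along
#' the vessel and at branch points. No centerline point enters the FAZ disc.
#'
#' @param field_px square field size in pixels (>= 64).
#' @param mm_per_pixel physical scale.
#' @param n_trees number of trees seeded on the field border.
#' @param branch_prob per-step probability that a tip spawns a side branch.
#' @param step_px centerline sampling step in pixels.
#' @param max_radius_px radius of trunk vessels at the border.
#' @param min_radius_px radius below which a branch terminates (>= 0.5).
#' @param faz_radius_mm FAZ radius in mm (>= 0).
#' @param seed integer seed; the same seed reproduces the same truth.
#' @return An object of class `vessel_truth`: `segments` (list of
#'   `list(points, radius)` with `points` an n x 2 matrix of (row, col)),
#'   `faz_center`, `faz_radius_px`, `field_px`, `mm_per_pixel`, `seed`.
#' @export
generate_vessel_truth <- function(field_px = 232L, mm_per_pixel = 3 / 232,
                                  n_trees = 8L, branch_prob = 0.10,
                                  step_px = 2, max_radius_px = 3.0,
                                  min_radius_px = 0.8, faz_radius_mm = 0.25,
                                  seed = 1L) {
  stopifnot(field_px >= 64, faz_radius_mm >= 0, is_count(n_trees))
  if (min_radius_px < 0.5) stopf("minimum vessel radius below 0.5 px is not renderable")
  faz_center <- c((field_px + 1) / 2, (field_px + 1) / 2)
  faz_r <- faz_radius_mm / mm_per_pixel
  segments <- list()

  with_seed(seed, {
    if (n_trees > 0) {
      # queue of active tips: position, direction (unit), radius, steps left
      tips <- list()
      for (t in seq_len(n_trees)) {
        side <- sample(4, 1)
        u <- runif(1, 0.1, 0.9) * field_px
        pos <- switch(side,
                      c(1, u), c(field_px, u), c(u, 1), c(u, field_px))
        dirv <- faz_center - pos + runif(2, -0.25, 0.25) * field_px
        dirv <- dirv / sqrt(sum(dirv^2))
        tips[[length(tips) + 1]] <- list(pos = pos, dir = dirv,
                                         r = runif(1, 0.75, 1) * max_radius_px,
                                         depth = 0)
      }
      max_steps <- ceiling(1.5 * field_px / step_px)
      while (length(tips) > 0) {
        tip <- tips[[1]]; tips[[1]] <- NULL
        pts <- matrix(tip$pos, 1, 2)
        rad <- tip$r
        pos <- tip$pos; dirv <- tip$dir; r <- tip$r
        for (s in seq_len(max_steps)) {
          # meander plus steering away from the FAZ disc
          ang <- rnorm(1, 0, 0.22)
          rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
          cand_dir <- as.numeric(rot %*% dirv)
          cand <- pos + step_px * cand_dir
          tries <- 0
          while (sqrt(sum((cand - faz_center)^2)) < faz_r + 1 && tries < 8) {
            away <- (pos - faz_center) / max(sqrt(sum((pos - faz_center)^2)), 1e-9)
            cand_dir <- cand_dir + 0.6 * away
            cand_dir <- cand_dir / sqrt(sum(cand_dir^2))
            cand <- pos + step_px * cand_dir
            tries <- tries + 1
          }
          if (tries >= 8) break
          if (any(cand < 1) || any(cand > field_px)) break
          pos <- cand; dirv <- cand_dir
          r <- r * 0.995
          if (r < min_radius_px) break
          pts <- rbind(pts, pos)
          rad <- c(rad, r)
          if (runif(1) < branch_prob && tip$depth < 4 && r * 0.7 >= min_radius_px) {
            bang <- sample(c(-1, 1), 1) * runif(1, 0.4, 1.1)
            brot <- matrix(c(cos(bang), sin(bang), -sin(bang), cos(bang)), 2, 2)
            tips[[length(tips) + 1]] <- list(pos = pos,
                                             dir = as.numeric(brot %*% dirv),
                                             r = r * 0.7, depth = tip$depth + 1)
            r <- r * 0.9
          }
        }
        if (nrow(pts) >= 2) {
          dimnames(pts) <- NULL
          segments[[length(segments) + 1]] <- list(points = pts, radius = rad)
        }
      }
    }
  })
  structure(list(segments = segments, faz_center = faz_center,
                 faz_radius_px = faz_r, field_px = as.integer(field_px),
                 mm_per_pixel = mm_per_pixel, seed = as.integer(seed)),
            class = "vessel_truth")
}

# Stamp anti-aliased discs of radius `rad[i]` centered at `pts[i, ]` onto
# canvas (max blend), returning the canvas. Coverage ramps linearly over the
# last pixel of the radius.
stamp_discs <- function(canvas, pts, rad, value = 1) {
  h <- nrow(canvas); w <- ncol(canvas)
  for (i in seq_len(nrow(pts))) {
    r <- rad[i]
    r0 <- max(1L, floor(pts[i, 1] - r - 1)); r1 <- min(h, ceiling(pts[i, 1] + r + 1))
    c0 <- max(1L, floor(pts[i, 2] - r - 1)); c1 <- min(w, ceiling(pts[i, 2] + r + 1))
    if (r0 > r1 || c0 > c1) next
    rr <- r0:r1; cc <- c0:c1
    d <- sqrt(outer((rr - pts[i, 1])^2, (cc - pts[i, 2])^2, "+"))
    cov <- clamp(r + 0.5 - d, 0, 1) * value
    canvas[rr, cc] <- pmax(canvas[rr, cc], cov)
  }
  canvas
}

faz_mask <- function(h, w, center, radius_px) {
  outer((seq_len(h) - center[1])^2, (seq_len(w) - center[2])^2, "+") <= radius_px^2
}

#' Render the noiseless en face image of a ground-truth vasculature
#'
#' Vessels are drawn as anti-aliased discs stamped along each centerline at
#' its local radius. Outside the FAZ a faint diffuse capillary-bed texture is
#' added at `bed_intensity`; the FAZ interior is exactly zero before noise.
#'
#' @param truth a [generate_vessel_truth()] result.
#' @param vessel_intensity peak vessel intensity in `(0, 1]`.
#' @param bed_intensity capillary-bed texture level in `[0, 1)`, below
#'   `vessel_intensity`.
#' @return An [enface_image()] with label `"clean"`.
#' @export
render_clean <- function(truth, vessel_intensity = 0.85, bed_intensity = 0.15) {
  stopifnot(inherits(truth, "vessel_truth"),
            vessel_intensity > 0, vessel_intensity <= 1,
            bed_intensity >= 0, bed_intensity < vessel_intensity)
  h <- truth$field_px; w <- truth$field_px
  canvas <- matrix(0, h, w)
  for (seg in truth$segments) {
    canvas <- stamp_discs(canvas, seg$points, seg$radius, vessel_intensity)
  }
  if (bed_intensity > 0) {
    # smooth random texture, deterministic in the truth's seed
    tex <- with_seed(derive_seed(truth$seed, 777), matrix(rnorm(h * w), h, w))
    k <- outer(stats::dnorm(-4:4, 0, 1.5), stats::dnorm(-4:4, 0, 1.5))
    tex <- as.matrix(EBImage::filter2(EBImage::Image(tex), k / sum(k)))
    tex <- (tex - min(tex)) / max(max(tex) - min(tex), 1e-12)
    canvas <- pmax(canvas, bed_intensity * (0.4 + 0.6 * tex))
  }
  canvas[faz_mask(h, w, truth$faz_center, truth$faz_radius_px)] <- 0
  img <- enface_image(quantize_8bit(canvas), mm_per_pixel = truth$mm_per_pixel,
                      label = "clean", seed = truth$seed,
                      provenance = "render_clean")
  img
}

# Build the multiplicative dropout field (1 = keep) for one frame: geometric
# runs of centerline points erased per segment with probability dropout_prob.
dropout_field <- function(truth, dropout_prob, h, w, offset = c(0, 0)) {
  keep <- matrix(1, h, w)
  if (dropout_prob <= 0) return(keep)
  gaps <- matrix(0, h, w)
  for (seg in truth$segments) {
    if (runif(1) >= dropout_prob) next
    n <- nrow(seg$points)
    start <- sample.int(n, 1)
    len <- min(n - start + 1, 1 + stats::rgeom(1, prob = 0.15))
    idx <- start:(start + len - 1)
    pts <- sweep(seg$points[idx, , drop = FALSE], 2, -offset)
    gaps <- stamp_discs(gaps, pts, seg$radius[idx] * 1.3, 1)
  }
  keep - 0.95 * gaps
}

#' Simulate one single-shot acquisition from a clean render
#'
#' Applies, in order: per-segment dropout gaps on the flow signal (when the
#' ground truth is supplied), pixelwise mean-one gamma speckle on the signal,
#' additive folded-normal background noise, then the optional shadow
#' attenuation and motion-line gain; the result is clipped and quantized to
#' 8 bits. Deterministic for a fixed seed.
#'
#' @param clean an [enface_image()] with label `"clean"`.
#' @param noise a [noise_params()].
#' @param seed integer seed for this frame.
#' @param truth optional [generate_vessel_truth()] result enabling dropout
#'   gaps (they are defined on centerline runs).
#' @param offset integer `(drow, dcol)` translation already applied to
#'   `clean`, so truth coordinates can be aligned.
#' @return An [enface_image()] with label `"original"`.
#' @export
simulate_single_shot <- function(clean, noise, seed, truth = NULL,
                                 offset = c(0L, 0L)) {
  stopifnot(inherits(clean, "enface_image"), inherits(noise, "noise_params"))
  if (clean$label != "clean") stopf("`clean` must have label 'clean'")
  h <- nrow(clean$pixels); w <- ncol(clean$pixels)
  with_seed(seed, {
    sig <- clean$pixels / 255
    if (!is.null(truth) && noise$dropout_prob > 0) {
      sig <- sig * dropout_field(truth, noise$dropout_prob, h, w, offset)
    }
    if (is.finite(noise$speckle_shape)) {
      sig <- sig * matrix(stats::rgamma(h * w, shape = noise$speckle_shape,
                                        rate = noise$speckle_shape), h, w)
    }
    if (noise$background_level > 0) {
      sig <- sig + abs(matrix(stats::rnorm(h * w, 0, noise$background_level), h, w))
    }
    if (!is.null(noise$shadow)) {
      sh <- noise$shadow
      m <- faz_mask(h, w, sweep_center(sh$center, offset), sh$radius_px)
      sig[m] <- sig[m] * sh$attenuation
    }
    if (!is.null(noise$motion_line)) {
      row <- noise$motion_line$row
      if (row >= 1 && row <= h) sig[row, ] <- sig[row, ] * noise$motion_line$gain
    }
    enface_image(quantize_8bit(sig), mm_per_pixel = clean$mm_per_pixel,
                 label = "original", seed = as.integer(seed),
                 provenance = "simulate_single_shot")
  })
}

sweep_center <- function(center, offset) c(center[1] + offset[1], center[2] + offset[2])

#' Simulate a full repeated-acquisition stack for one synthetic eye
#'
#' Generates a ground truth and clean render, then `n_frames` single shots
#' with independent noise and independent integer translations drawn
#' uniformly from the jitter bound. Frame 1 is the "original" by convention
#' and its offset is forced to `(0, 0)`.
#'
#' @param n_frames number of repeated frames (>= 1); 10 matches the repeated
#'   acquisition protocol the package emulates.
#' @param noise a [noise_params()].
#' @param seed master seed for the eye.
#' @param field_px,mm_per_pixel,n_trees,faz_radius_mm,... forwarded to
#'   [generate_vessel_truth()].
#' @param vessel_intensity,bed_intensity forwarded to [render_clean()].
#' @return An object of class `frame_stack`: `frames` (list of
#'   [enface_image()]), `true_offsets` (n x 2 integer matrix), `clean`,
#'   `truth`, `seed`.
#' @export
simulate_eye <- function(n_frames = 10L, noise = noise_params(), seed = 1L,
                         field_px = 232L, mm_per_pixel = 3 / 232,
                         n_trees = 8L, faz_radius_mm = 0.25,
                         vessel_intensity = 0.85, bed_intensity = 0.15, ...) {
  stopifnot(n_frames >= 1)
  if (noise$jitter_max_px >= field_px / 4) {
    stopf("jitter bound %d px is too large for a %d px field (unregisterable)",
          noise$jitter_max_px, field_px)
  }
  truth <- generate_vessel_truth(field_px = field_px, mm_per_pixel = mm_per_pixel,
                                 n_trees = n_trees, faz_radius_mm = faz_radius_mm,
                                 seed = derive_seed(seed, 1), ...)
  clean <- render_clean(truth, vessel_intensity, bed_intensity)
  offsets <- with_seed(derive_seed(seed, 2), {
    vals <- seq.int(-noise$jitter_max_px, noise$jitter_max_px)
    o <- matrix(vals[sample.int(length(vals), 2 * n_frames, replace = TRUE)],
                n_frames, 2)
    o[1, ] <- c(0L, 0L)
    o
  })
  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    shifted <- clean
    if (any(offsets[i, ] != 0)) {
      shifted <- enface_image(shift_matrix(clean$pixels, offsets[i, ]),
                              mm_per_pixel = clean$mm_per_pixel, label = "clean",
                              seed = clean$seed, provenance = clean$provenance)
    }
    frames[[i]] <- simulate_single_shot(shifted, noise,
                                        seed = derive_seed(seed, 100 + i),
                                        truth = truth, offset = offsets[i, ])
  }
  structure(list(frames = frames, true_offsets = offsets, clean = clean,
                 truth = truth, seed = as.integer(seed)),
            class = "frame_stack")
}
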