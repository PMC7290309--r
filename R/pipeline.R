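#' Configuration of a synthetic original/averaged/denoised experiment
#'
#' Bundles everything needed to rerun the full pipeline on a simulated
#' cohort: simulate training eyes, train the denoiser on (single-shot,
#' averaged) pairs, then score held-out test eyes. Training and test eyes
#' draw from disjoint seed streams.
#'
#' @param n_train_eyes eyes used to build training pairs (default 20).
#' @param n_test_eyes held-out eyes scored by the metrics (default 10).
#' @param n_frames repeated frames per eye (default 10).
#' @param noise a [noise_params()].
#' @param denoiser a [denoiser_config()].
#' @param seed master seed for the whole experiment.
#' @param field_px field size in pixels.
#' @param max_shift registration search bound; defaults to the jitter bound
#'   plus 2 px.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_train_eyes = 20L, n_test_eyes = 10L,
                              n_frames = 10L, noise = noise_params(),
                              denoiser = denoiser_config(), seed = 1L,
                              field_px = 232L, max_shift = NULL) {
  stopifnot(is_count(n_train_eyes), is_count(n_test_eyes), n_frames >= 1)
  if (is.null(max_shift)) max_shift <- noise$jitter_max_px + 2L
  structure(list(n_train_eyes = as.integer(n_train_eyes),
                 n_test_eyes = as.integer(n_test_eyes),
                 n_frames = as.integer(n_frames), noise = noise,
                 denoiser = denoiser, seed = as.integer(seed),
                 field_px = as.integer(field_px),
                 max_shift = as.integer(max_shift)),
            class = "experiment_config")
}

simulate_and_average <- function(cfg, eye_seed) {
  stack <- simulate_eye(n_frames = cfg$n_frames, noise = cfg$noise,
                        seed = eye_seed, field_px = cfg$field_px)
  reg <- register_frames(stack, max_shift = cfg$max_shift)
  avg <- average_frames(stack, reg)
  list(stack = stack, averaged = avg, original = stack$frames[[1]])
}

#' Run the full synthetic experiment
#'
#' Simulates the training cohort, trains the denoiser with single-shot
#' frames as input and registered averaged images as teacher, then for each
#' held-out test eye produces the original/averaged/denoised triplet and
#' computes CNR (one ROI set placed per eye and reused across the three
#' images), PSNR of the original and denoised images against the averaged
#' reference, and VD/VLD/VDI/FD on binarized (500 x 500) and skeletonized
#' images. Fully reproducible from `config$seed`.
#'
#' @param config an [experiment_config()].
#' @param verbose print stage progress.
#' @return A list with `metrics` (data.frame, one row per eye x image
#'   label), `report` (the [compare_groups()] result), `model` (the trained
#'   denoiser), `config`.
#' @export
run_experiment <- function(config = experiment_config(), verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  pairs <- vector("list", config$n_train_eyes)
  for (i in seq_len(config$n_train_eyes)) {
    eye <- tryCatch(
      simulate_and_average(config, derive_seed(config$seed, i)),
      error = function(e) stopf("train eye %d, simulation/averaging: %s", i, conditionMessage(e)))
    pairs[[i]] <- extract_patches(eye$original, eye$averaged, config$denoiser,
                                  eye_id = sprintf("train%02d", i))
  }
  say("simulated %d training eyes [%.1f s]", config$n_train_eyes,
      as.numeric(Sys.time() - t0, units = "secs"))
  model <- train_denoiser(combine_pairs(pairs), config$denoiser, verbose = verbose)
  say("trained denoiser, final loss %.5f [%.1f s]", model$final_loss,
      as.numeric(Sys.time() - t0, units = "secs"))

  rows <- list()
  for (i in seq_len(config$n_test_eyes)) {
    eye_id <- sprintf("test%02d", i)
    eye <- tryCatch(
      simulate_and_average(config, derive_seed(config$seed, 10000 + i)),
      error = function(e) stopf("%s, simulation/averaging: %s", eye_id, conditionMessage(e)))
    den <- denoise_image(model, eye$original)
    triplet <- list(original = eye$original, averaged = eye$averaged,
                    denoised = den)
    rois <- place_cnr_rois(eye$original)
    for (lab in names(triplet)) {
      img <- triplet[[lab]]
      ps <- if (lab == "averaged") NA_real_ else psnr(img, eye$averaged)$psnr_db
      mask <- binarize(img, resample_to_500 = TRUE)
      skel <- skeletonize_mask(mask)
      rows[[length(rows) + 1]] <- data.frame(
        eye = eye_id, label = lab,
        cnr = cnr(img, rois)$cnr_value,
        psnr_db = ps,
        vd = vessel_density(mask),
        vld = vessel_length_density(skel),
        vdi = vessel_diameter_index(mask, skel),
        fd = fractal_dimension(skel),
        stringsAsFactors = FALSE)
    }
    say("scored %s [%.1f s]", eye_id, as.numeric(Sys.time() - t0, units = "secs"))
  }
  metrics <- do.call(rbind, rows)
  metrics$label <- factor(metrics$label, levels = c("original", "averaged", "denoised"))
  list(metrics = metrics, report = compare_groups(metrics), model = model,
       config = config)
}

#' Group comparison report across original/averaged/denoised images
#'
#' For VD, VLD, VDI, FD and CNR: one-way ANOVA across the three image labels
#' with Tukey HSD adjusted pairwise p-values. PSNR (defined only for the
#' original and denoised images, which are both scored against the averaged
#' reference) is compared by a paired t-test. All groups are summarized as
#' mean +/- SD.
#'
#' @param metrics a metrics data.frame as produced by [run_experiment()]
#'   (columns `eye`, `label`, and the metric columns).
#' @return An object of class `stats_report`: `group_means` (data.frame of
#'   metric, label, mean, sd, n) and `comparisons` (data.frame of metric,
#'   pair, p_adj, method).
#' @export
compare_groups <- function(metrics) {
  stopifnot(is.data.frame(metrics))
  need <- c("eye", "label")
  if (!all(need %in% names(metrics))) stopf("metrics must have 'eye' and 'label' columns")
  metrics$label <- factor(as.character(metrics$label),
                          levels = c("original", "averaged", "denoised"))
  if (anyNA(metrics$label) || !all(levels(metrics$label) %in% metrics$label)) {
    stopf("metrics must contain all three labels: original, averaged, denoised")
  }
  counts <- table(metrics$label)
  if (any(counts < 3)) stopf("need at least 3 eyes per group")
  if (length(unique(counts)) != 1) stopf("unbalanced groups")

  anova_metrics <- intersect(c("vd", "vld", "vdi", "fd", "cnr"), names(metrics))
  means <- list(); comps <- list()
  for (mname in anova_metrics) {
    v <- metrics[[mname]]
    for (lab in levels(metrics$label)) {
      x <- v[metrics$label == lab]
      means[[length(means) + 1]] <- data.frame(
        metric = mname, label = lab, mean = mean(x), sd = stats::sd(x),
        n = length(x), stringsAsFactors = FALSE)
    }
    if (stats::var(v) < .Machine$double.eps) {
      # identical groups: no spread, no effect
      prs <- c("averaged-original", "denoised-original", "denoised-averaged")
      for (pr in prs) {
        comps[[length(comps) + 1]] <- data.frame(
          metric = mname, pair = pr, p_adj = 1, method = "Tukey HSD",
          stringsAsFactors = FALSE)
      }
      next
    }
    fit <- stats::aov(v ~ label, data = data.frame(v = v, label = metrics$label))
    tk <- stats::TukeyHSD(fit)$label
    for (pr in rownames(tk)) {
      comps[[length(comps) + 1]] <- data.frame(
        metric = mname, pair = pr, p_adj = tk[pr, "p adj"],
        method = "Tukey HSD", stringsAsFactors = FALSE)
    }
  }
  if ("psnr_db" %in% names(metrics)) {
    sub <- metrics[metrics$label %in% c("original", "denoised"), ]
    sub <- sub[order(sub$eye, sub$label), ]
    orig <- sub$psnr_db[sub$label == "original"]
    den <- sub$psnr_db[sub$label == "denoised"]
    for (lab in c("original", "denoised")) {
      x <- sub$psnr_db[sub$label == lab]
      means[[length(means) + 1]] <- data.frame(
        metric = "psnr_db", label = lab, mean = mean(x), sd = stats::sd(x),
        n = length(x), stringsAsFactors = FALSE)
    }
    p <- if (isTRUE(all.equal(orig, den))) 1 else
      stats::t.test(den, orig, paired = TRUE)$p.value
    comps[[length(comps) + 1]] <- data.frame(
      metric = "psnr_db", pair = "denoised-original", p_adj = p,
      method = "paired t-test", stringsAsFactors = FALSE)
  }
  structure(list(group_means = do.call(rbind, means),
                 comparisons = do.call(rbind, comps)),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat("Group means (mean +/- SD):\n")
  gm <- x$group_means
  for (mname in unique(gm$metric)) {
    rows <- gm[gm$metric == mname, ]
    cat(sprintf("  %-8s %s\n", mname,
                paste(sprintf("%s %.4g +/- %.3g", rows$label, rows$mean, rows$sd),
                      collapse = " | ")))
  }
  cat("Pairwise comparisons:\n")
  cm <- x$comparisons
  for (i in seq_len(nrow(cm))) {
    cat(sprintf("  %-8s %-20s p = %.4g  (%s)\n", cm$metric[i], cm$pair[i],
                cm$p_adj[i], cm$method[i]))
  }
  invisible(x)
}
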