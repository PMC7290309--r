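test_that("patch grids cover the image with aligned origins", {
  st <- simulate_eye(seed = 23L, n_frames = 2L)
  avg <- average_frames(st)
  cfg <- denoiser_config()
  pairs <- extract_patches(st$frames[[1]], avg, cfg)
  # 232 px at patch 64 / stride 32: origins 1, 33, ..., 161 plus final 169
  expect_equal(dim(pairs$noisy)[3], 49)
  expect_identical(sort(unique(pairs$origins[, 1])),
                   c(seq(1L, 161L, by = 32L), 169L))
  same <- extract_patches(st$frames[[1]], st$frames[[1]], cfg)
  expect_equal(max(abs(same$noisy - same$teacher)), 0)
  small <- enface_image(matrix(0L, 32, 32))
  expect_error(extract_patches(small, small, cfg), "smaller than patch")
})

test_that("configuration invariants are enforced", {
  expect_error(denoiser_config(patch_px = 60L), "divisible")
  expect_error(denoiser_config(stride_px = 80L), "exceed")
  cfg <- denoiser_config(n_steps = 0L)
  p <- structure(list(noisy = array(0.5, c(64, 64, 2)),
                      teacher = array(0.5, c(64, 64, 2)),
                      origins = matrix(1L, 2, 2), eye_id = c("a", "a"),
                      patch_px = 64L), class = "training_pairs")
  expect_error(train_denoiser(p, cfg), "no training performed")
})

test_that("training is seed-reproducible and the loss decreases", {
  st <- simulate_eye(seed = 31L, field_px = 96L, n_frames = 4L)
  reg <- register_frames(st, max_shift = 4L)
  avg <- average_frames(st, reg)
  cfg <- denoiser_config(depth = 2L, base_channels = 4L, patch_px = 32L,
                         stride_px = 32L, n_steps = 40L, seed = 7L)
  pairs <- extract_patches(st$frames[[1]], avg, cfg)
  m1 <- train_denoiser(pairs, cfg)
  m2 <- train_denoiser(pairs, cfg)
  expect_equal(m1$loss_history, m2$loss_history, tolerance = 1e-5)
  expect_true(all(is.finite(m1$loss_history)))
  expect_lt(mean(tail(m1$loss_history, 5)), mean(head(m1$loss_history, 5)))
})

test_that("inference keeps dimensions, range, and scale", {
  st <- simulate_eye(seed = 37L, field_px = 96L, n_frames = 2L)
  cfg <- denoiser_config(depth = 2L, base_channels = 4L, patch_px = 32L,
                         stride_px = 32L, n_steps = 15L, seed = 7L)
  pairs <- extract_patches(st$frames[[1]], average_frames(st), cfg)
  m <- train_denoiser(pairs, cfg)
  den <- denoise_image(m, st$frames[[1]])
  expect_identical(dim(den$pixels), dim(st$frames[[1]]$pixels))
  expect_true(all(den$pixels >= 0 & den$pixels <= 255))
  expect_identical(den$label, "denoised")
  expect_equal(den$mm_per_pixel, st$frames[[1]]$mm_per_pixel)
  m64 <- m
  m64$config$patch_px <- 64L
  expect_error(denoise_image(m64, enface_image(matrix(0L, 32, 48))),
               "smaller than patch")
})

test_that("checkpoint save/load reproduces inference pixel-exactly", {
  st <- simulate_eye(seed = 41L, field_px = 96L, n_frames = 2L)
  cfg <- denoiser_config(depth = 2L, base_channels = 4L, patch_px = 32L,
                         stride_px = 32L, n_steps = 10L, seed = 3L)
  pairs <- extract_patches(st$frames[[1]], average_frames(st), cfg)
  m <- train_denoiser(pairs, cfg)
  path <- file.path(withr::local_tempdir(), "model.rds")
  save_denoiser(m, path)
  m2 <- load_denoiser(path)
  d1 <- denoise_image(m, st$frames[[1]])
  d2 <- denoise_image(m2, st$frames[[1]])
  expect_identical(d1$pixels, d2$pixels)
})

test_that("backpropagation matches numeric differentiation", {
  net <- octava:::unet_init(depth = 2, base_channels = 3, seed = 5)
  cache <- new.env(parent = emptyenv())
  set.seed(2)
  x <- matrix(runif(8 * 8 * 2), ncol = 1)
  y <- matrix(runif(8 * 8 * 2), ncol = 1)
  fw <- octava:::unet_forward(net, x, 8, 8, 2, cache, keep = TRUE)
  d <- fw$pred - y
  loss0 <- mean(d^2)
  grads <- octava:::grad_params(
    octava:::unet_backward(net, fw, 2 * d / length(d)), net)
  params <- octava:::net_params(net)
  eps <- 1e-6
  for (nm in names(params)) {
    i <- ((7 * seq_along(params[[nm]])[1]) %% length(params[[nm]])) + 1
    bumped <- params
    bumped[[nm]][i] <- bumped[[nm]][i] + eps
    fw2 <- octava:::unet_forward(octava:::set_net_params(net, bumped),
                                 x, 8, 8, 2, cache)
    num <- (mean((fw2$pred - y)^2) - loss0) / eps
    expect_equal(grads[[nm]][i], num, tolerance = 1e-4,
                 label = sprintf("gradient of %s", nm))
  }
})
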