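test_that("binarization separates a two-valued image at its modes", {
  px <- matrix(0L, 64, 64)
  px[20:40, 10:50] <- 200L
  mk <- binarize(enface_image(px))
  # median prefilter preserves the interior; compare away from the boundary
  expect_true(all(mk$mask[21:39, 11:49]))
  expect_true(all(!mk$mask[1:18, ]))
})

test_that("resampling to the 500 x 500 export grid rescales mask and scale", {
  st <- simulate_eye(seed = 3L, n_frames = 1L)
  mk <- binarize(st$frames[[1]], resample_to_500 = TRUE)
  expect_identical(dim(mk$mask), c(500L, 500L))
  expect_equal(mk$mm_per_pixel, 3 / 500, tolerance = 1e-12)
})

test_that("constant images binarize to an empty mask with a warning", {
  expect_warning(mk <- binarize(enface_image(matrix(7L, 64, 64))), "constant")
  expect_false(any(mk$mask))
})

test_that("skeletonization thins a solid bar to a single one-pixel path", {
  m <- matrix(FALSE, 64, 64)
  m[30:33, 10:49] <- TRUE
  sk <- skeletonize_mask(mask_from_matrix(m))
  expect_true(all(sk$mask[m == FALSE] == FALSE))   # skeleton within mask
  expect_true(all(rowSums(sk$mask)[c(1:28, 36:64)] == 0))
  npix <- sum(sk$mask)   # endpoints may erode a little during thinning
  expect_gte(npix, 34); expect_lte(npix, 40)
  # one pixel per column over the bar interior
  expect_true(all(colSums(sk$mask)[12:47] == 1))
})

test_that("skeleton has no 2x2 solid block and keeps isolated pixels", {
  m <- matrix(FALSE, 64, 64)
  m[10:20, 10:20] <- TRUE   # solid square
  m[50, 50] <- TRUE         # isolated pixel
  sk <- skeletonize_mask(mask_from_matrix(m))
  s <- sk$mask
  blocks <- s[1:63, 1:63] & s[2:64, 1:63] & s[1:63, 2:64] & s[2:64, 2:64]
  expect_false(any(blocks))
  expect_true(s[50, 50])
  empty <- skeletonize_mask(mask_from_matrix(matrix(FALSE, 64, 64)))
  expect_false(any(empty$mask))
})

test_that("vessel density is the exact true-pixel fraction", {
  expect_equal(vessel_density(mask_from_matrix(matrix(TRUE, 50, 50))), 1)
  expect_equal(vessel_density(mask_from_matrix(matrix(FALSE, 50, 50))), 0)
  m <- matrix(FALSE, 50, 50); m[1:25, 1:25] <- TRUE
  expect_equal(vessel_density(mask_from_matrix(m)), 0.25)
})

test_that("vessel length density follows the 8-neighbor step rule", {
  expect_equal(vessel_length_density(
    skeleton_from_matrix(matrix(FALSE, 500, 500), 3 / 500)), 0)
  m <- matrix(FALSE, 500, 500); m[250, ] <- TRUE
  vld <- vessel_length_density(skeleton_from_matrix(m, 3 / 500))
  expect_equal(vld, 1 / 3, tolerance = 0.01)
  d <- matrix(FALSE, 500, 500); d[cbind(1:500, 1:500)] <- TRUE
  vld_d <- vessel_length_density(skeleton_from_matrix(d, 3 / 500))
  expect_equal(vld_d, sqrt(2) / 3, tolerance = 0.02)
})

test_that("vessel diameter index recovers bar width and scales with it", {
  bar_mask <- function(width) {
    m <- matrix(FALSE, 64, 64)
    m[30:(29 + width), 10:49] <- TRUE
    mask_from_matrix(m)
  }
  m4 <- bar_mask(4)
  vdi4 <- vessel_diameter_index(m4, skeletonize_mask(m4))
  expect_equal(vdi4, 4, tolerance = 0.15 * 4)
  m8 <- bar_mask(8)
  vdi8 <- vessel_diameter_index(m8, skeletonize_mask(m8))
  expect_equal(vdi8 / vdi4, 2, tolerance = 0.25)
  expect_error(
    vessel_diameter_index(m4, skeleton_from_matrix(matrix(FALSE, 64, 64))),
    "undefined")
})

test_that("fractal dimension brackets the line and the filled plane", {
  line <- matrix(FALSE, 256, 256); line[128, ] <- TRUE
  fd_line <- fractal_dimension(skeleton_from_matrix(line, 3 / 256))
  expect_equal(fd_line, 1, tolerance = 0.1)
  filled <- matrix(TRUE, 256, 256)
  fd_fill <- fractal_dimension(skeleton_from_matrix(filled, 3 / 256))
  expect_equal(fd_fill, 2, tolerance = 0.05)
  expect_lte(fd_fill, 2)
  expect_warning(
    fd0 <- fractal_dimension(skeleton_from_matrix(matrix(FALSE, 256, 256))),
    "empty")
  expect_equal(fd0, 0)
})

test_that("fractal dimension grows as branches are added to a line", {
  base <- matrix(FALSE, 256, 256)
  base[128, ] <- TRUE
  one <- base; one[, 128] <- TRUE
  many <- one
  for (cc in seq(16, 240, by = 32)) many[64:192, cc] <- TRUE
  fds <- vapply(list(base, one, many), function(m) {
    fractal_dimension(skeleton_from_matrix(m, 3 / 256))
  }, 0)
  expect_true(all(diff(fds) > 0))
  expect_true(all(fds >= 0 & fds <= 2))
})

test_that("metrics ignore the image label metadata", {
  st <- simulate_eye(seed = 17L, n_frames = 1L, field_px = 96L)
  img <- st$frames[[1]]
  relabeled <- img; relabeled$label <- "denoised"
  m1 <- binarize(img); m2 <- binarize(relabeled)
  expect_identical(m1$mask, m2$mask)
  s1 <- skeletonize_mask(m1)
  expect_equal(vessel_length_density(s1),
               vessel_length_density(skeletonize_mask(m2)))
})
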