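test_that("default ROI discs rasterize to about 314 square pixels", {
  img <- enface_image(matrix(0L, 232, 232))
  rois <- place_cnr_rois(img)
  counts <- c(nrow(rois$background$pixels),
              vapply(rois$foreground, function(r) nrow(r$pixels), 0L))
  expect_length(counts, 5)
  expect_true(all(counts >= 305 & counts <= 325))
})

test_that("tiny discs enumerate the lattice points within the radius", {
  img <- enface_image(matrix(0L, 64, 64))
  rois <- place_cnr_rois(img, faz_center = c(32, 32), diameter_px = 2L,
                         corner_inset_px = 5L)
  # radius 1 around an integer center: the 5-point plus shape
  expect_equal(nrow(rois$background$pixels), 5)
  d <- sqrt((rois$background$pixels[, 1] - 32)^2 +
              (rois$background$pixels[, 2] - 32)^2)
  expect_true(all(d <= 1))
})

test_that("out-of-bounds ROI placements error", {
  img <- enface_image(matrix(0L, 64, 64))
  expect_error(place_cnr_rois(img, corner_inset_px = 30L), "does not fit")
  expect_error(place_cnr_rois(img, faz_center = c(5, 5)), "outside")
})

test_that("cnr reproduces the closed-form hand case", {
  # foreground pixels at mean 150 with population SD 4, background mean 50
  # with SD 3 -> CNR = (150 - 50) / sqrt(16 + 9) = 20
  px <- matrix(50L, 232, 232)
  img0 <- enface_image(px)
  rois <- place_cnr_rois(img0)
  for (fg in rois$foreground) {
    n <- nrow(fg$pixels)
    half <- seq_len(n) <= n / 2
    px[fg$pixels] <- ifelse(half, 154L, 146L)   # mean 150, SD 4
  }
  bg <- rois$background$pixels
  nb <- nrow(bg)
  px[bg] <- ifelse(seq_len(nb) <= nb / 2, 53L, 47L)  # mean 50, SD 3
  img <- enface_image(px)
  out <- cnr(img, rois)
  expect_equal(out$stats$f, 150, tolerance = 1e-2)
  expect_equal(out$stats$b, 50, tolerance = 1e-2)
  expect_equal(out$cnr_value, 20, tolerance = 0.02)
})

test_that("cnr degenerate cases follow the declared conventions", {
  img <- enface_image(matrix(77L, 232, 232))
  expect_equal(cnr(img)$cnr_value, 0)
  # zero spread but unequal means is a degenerate geometry
  px <- matrix(50L, 232, 232)
  rois <- place_cnr_rois(enface_image(px))
  for (fg in rois$foreground) px[fg$pixels] <- 150L
  expect_error(cnr(enface_image(px), rois), "degenerate")
})

test_that("cnr is shift-invariant and sign-flips under negation", {
  img <- small_clean_eye()
  expect_lte(max(img$pixels) + 20, 255)   # no clipping below
  rois <- place_cnr_rois(img)
  v0 <- cnr(img, rois)$cnr_value
  shifted <- enface_image(img$pixels + 20L)
  expect_equal(cnr(shifted, rois)$cnr_value, v0, tolerance = 1e-12)
  negated <- enface_image(255L - img$pixels)
  expect_equal(cnr(negated, rois)$cnr_value, -v0, tolerance = 1e-12)
})

test_that("psnr matches direct formula evaluation", {
  a <- enface_image(matrix(100L, 64, 64))
  expect_true(is.infinite(psnr(a, a)$psnr_db))
  b255 <- enface_image(matrix(0L, 64, 64))
  a255 <- enface_image(matrix(255L, 64, 64))
  expect_equal(psnr(a255, b255)$psnr_db, 0)
  b16 <- enface_image(matrix(116L, 64, 64))
  out <- psnr(a, b16)
  expect_equal(out$mse, 256)
  expect_equal(out$psnr_db, 10 * log10(255^2 / 256), tolerance = 1e-12)
})

test_that("psnr is symmetric and decreases with perturbation size", {
  img <- small_clean_eye()
  pert <- function(d) enface_image(pmin(img$pixels + d, 255L))
  p1 <- psnr(img, pert(8L))$psnr_db
  expect_equal(p1, psnr(pert(8L), img)$psnr_db)
  p2 <- psnr(img, pert(16L))$psnr_db
  p3 <- psnr(img, pert(32L))$psnr_db
  expect_true(p1 > p2 && p2 > p3)
  expect_error(psnr(img, enface_image(matrix(0L, 48, 48))), "dimensions")
})
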