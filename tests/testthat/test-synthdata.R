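test_that("vessel truth generation is seed-deterministic", {
  t1 <- generate_vessel_truth(field_px = 96L, n_trees = 4L, seed = 5L)
  t2 <- generate_vessel_truth(field_px = 96L, n_trees = 4L, seed = 5L)
  expect_identical(t1$segments, t2$segments)
  t3 <- generate_vessel_truth(field_px = 96L, n_trees = 4L, seed = 6L)
  expect_false(identical(t1$segments, t3$segments))
})

test_that("no centerline point enters the FAZ disc (exhaustive scan)", {
  tr <- generate_vessel_truth(field_px = 232L, n_trees = 8L,
                              faz_radius_mm = 0.3, seed = 21L)
  faz_px <- 0.3 / tr$mm_per_pixel
  for (seg in tr$segments) {
    d <- sqrt((seg$points[, 1] - tr$faz_center[1])^2 +
                (seg$points[, 2] - tr$faz_center[2])^2)
    expect_true(all(d >= faz_px))
    expect_true(all(seg$radius > 0))
    expect_true(all(seg$points >= 1 & seg$points <= tr$field_px))
  }
})

test_that("zero trees gives a valid empty truth and an all-zero flat render", {
  tr <- generate_vessel_truth(field_px = 96L, n_trees = 0L, seed = 1L)
  expect_length(tr$segments, 0)
  img <- render_clean(tr, vessel_intensity = 0.9, bed_intensity = 0)
  expect_true(all(img$pixels == 0L))
})

test_that("sub-renderable radii are rejected", {
  expect_error(generate_vessel_truth(min_radius_px = 0.3, seed = 1L), "0.5 px")
})

test_that("a straight horizontal vessel renders at its nominal width", {
  tr <- structure(list(
    segments = list(list(points = cbind(rep(48, 60), 11:70),
                         radius = rep(2, 60))),
    faz_center = c(1000, 1000), faz_radius_px = 0,
    field_px = 96L, mm_per_pixel = 3 / 96, seed = 1L),
    class = "vessel_truth")
  img <- render_clean(tr, vessel_intensity = 1, bed_intensity = 0)
  widths <- colSums(img$pixels[, 20:60] > 127)
  expect_true(all(widths >= 3 & widths <= 5))
})

test_that("single-shot simulation is seeded and identity when noise is off", {
  cl <- small_clean_eye()
  f1 <- simulate_single_shot(cl, noise_params(), seed = 3L)
  f2 <- simulate_single_shot(cl, noise_params(), seed = 3L)
  f3 <- simulate_single_shot(cl, noise_params(), seed = 4L)
  expect_identical(f1$pixels, f2$pixels)
  expect_false(identical(f1$pixels, f3$pixels))
  id <- simulate_single_shot(cl, noise_off(), seed = 3L)
  expect_identical(id$pixels, cl$pixels)
})

test_that("background noise raises the FAZ mean and does so monotonically", {
  tr <- generate_vessel_truth(field_px = 96L, n_trees = 4L, seed = 7L)
  cl <- render_clean(tr)
  faz <- outer((seq_len(96) - tr$faz_center[1])^2,
               (seq_len(96) - tr$faz_center[2])^2, "+") <= tr$faz_radius_px^2
  expect_lt(mean(cl$pixels[faz]), 1)
  means <- vapply(c(0.05, 0.15, 0.3), function(lvl) {
    f <- simulate_single_shot(cl, noise_params(background_level = lvl),
                              seed = 11L, truth = tr)
    mean(f$pixels[faz])
  }, 0)
  expect_gt(means[2], 5)
  expect_true(all(diff(means) > 0))
})

test_that("simulate_eye obeys the frame-count and jitter contracts", {
  st <- simulate_eye(n_frames = 10L, seed = 2L, field_px = 96L,
                     noise = noise_params(jitter_max_px = 3L))
  expect_length(st$frames, 10)
  expect_identical(st$true_offsets[1, ], c(0L, 0L))
  expect_true(all(abs(st$true_offsets) <= 3))
  still <- simulate_eye(n_frames = 3L, seed = 2L, field_px = 96L,
                        noise = noise_off())
  for (f in still$frames) expect_identical(f$pixels, still$clean$pixels)
  expect_error(simulate_eye(seed = 1L, field_px = 96L,
                            noise = noise_params(jitter_max_px = 30L)),
               "unregisterable")
})

test_that("shadow attenuation darkens vessels inside the shadow disc", {
  sh <- list(center = c(60, 60), radius_px = 30, attenuation = 0.3)
  st <- simulate_eye(n_frames = 1L, seed = 8L, field_px = 232L,
                     noise = noise_params(jitter_max_px = 0L, shadow = sh))
  vessel <- st$clean$pixels > 150
  disc <- outer((seq_len(232) - 60)^2, (seq_len(232) - 60)^2, "+") <= 30^2
  px <- st$frames[[1]]$pixels
  inside <- mean(px[vessel & disc])
  outside <- mean(px[vessel & !disc])
  expect_lt(inside, 0.6 * outside)
})
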