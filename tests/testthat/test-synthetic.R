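test_that("scene generation is a pure function of its configuration", {
  cfg <- small_scene_config(n_insects = 2, n_frames = 3, seed = 77)
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$frames, b$frames)
  expect_identical(a$truth, b$truth)

  c2 <- generate_scene(small_scene_config(n_insects = 2, n_frames = 3,
                                          seed = 78))
  expect_false(identical(a$frames[[1]], c2$frames[[1]]))

  # written frames are byte-identical across runs too
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- generate_scene(cfg, dir = d1)$frames
  f2 <- generate_scene(cfg, dir = d2)$frames
  expect_identical(readBin(f1[1], "raw", file.size(f1[1])),
                   readBin(f2[1], "raw", file.size(f2[1])))
})

test_that("an empty scene renders only the sheet", {
  cfg <- small_scene_config(n_insects = 0, n_frames = 2, seed = 5)
  scene <- generate_scene(cfg)
  expect_equal(nrow(scene$truth), 0)
  expect_identical(scene$frames[[1]], scene_background(scene))
})

test_that("insects too large for the frame are rejected", {
  cfg <- scene_config(width = 100, height = 100, n_insects = 1,
                      bbox_mean = c(368, 353), bbox_sd = 0, seed = 1)
  expect_error(generate_scene(cfg), "cannot fit")
})

test_that("sampled bounding boxes follow the configured size distribution", {
  cfg <- scene_config(seed = 1)
  dims <- withr::with_seed(91, mothtrap:::sample_bbox_dims(1000, cfg))
  expect_gt(suppressWarnings(stats::ks.test(dims[, 1], "pnorm", 368, 110))$p.value,
            0.001)
  expect_gt(suppressWarnings(stats::ks.test(dims[, 2], "pnorm", 353, 110))$p.value,
            0.001)
  expect_true(all(dims >= cfg$bbox_min))
})

test_that("truth table geometry is consistent", {
  cfg <- small_scene_config(n_insects = 3, n_frames = 5, seed = 31)
  scene <- generate_scene(cfg)
  tr <- scene$truth
  expect_equal(tr$cx, tr$x_min + tr$width / 2)
  expect_equal(tr$cy, tr$y_min + tr$height / 2)
  expect_true(all(tr$x_min >= 0 & tr$x_min + tr$width <= cfg$width))
  expect_true(all(tr$y_min >= 0 & tr$y_min + tr$height <= cfg$height))
  expect_true(all(tr$species %in% moth_classes()))
  # each individual appears at most once per frame
  expect_equal(anyDuplicated(tr[, c("individual_id", "frame_index")]), 0)
})

test_that("crop datasets are balanced, sized and seeded", {
  crops <- generate_crop_dataset(n_classes = 4, n_per_class = 6, seed = 3,
                                 size = 32)
  expect_equal(nrow(crops), 24)
  expect_equal(as.vector(table(crops$class)), rep(6, 4))
  expect_equal(dim(crops$image[[1]]), c(32, 32, 3))
  crops2 <- generate_crop_dataset(n_classes = 4, n_per_class = 6, seed = 3,
                                  size = 32)
  expect_identical(crops, crops2)
})

test_that("synthetic classes separate even on mean color alone", {
  crops <- generate_crop_dataset(n_classes = 2, n_per_class = 10, seed = 17,
                                 size = 32)
  feats <- t(sapply(crops$image, function(im) {
    x <- crop_raster(im)
    c(mean(x[, , 1]), mean(x[, , 2]), mean(x[, , 3]))
  }))
  lab <- as.integer(crops$class)
  centroids <- rbind(colMeans(feats[lab == 1, ]), colMeans(feats[lab == 2, ]))
  pred <- apply(feats, 1, function(f) {
    which.min(c(sum((f - centroids[1, ])^2), sum((f - centroids[2, ])^2)))
  })
  expect_equal(pred, lab)   # nearest-centroid classifier is perfect
})
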