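test_that("motion gate counts changed pixels with a strict threshold", {
  a <- matrix(0.5, 100, 100)
  expect_false(motion_gate(a, a, threshold = 1500))

  b <- a
  b[1:50, 1:50] <- 1   # 2500 fully changed pixels
  expect_true(motion_gate(b, a, threshold = 1500))
  expect_false(motion_gate(b, a, threshold = 2500))  # strict inequality

  expect_error(motion_gate(a, matrix(0.5, 50, 50)), "mismatch")
})

test_that("foreground is a symmetric absolute difference with local support", {
  bg <- matrix(1, 60, 40)
  expect_equal(foreground(bg, bg), matrix(0, 60, 40))

  img <- bg
  d <- disk_raster(60, 40, 30, 20, 8)
  img[d == 1] <- 0.1
  fg <- foreground(img, bg)
  expect_true(all(fg[d == 1] > 0))
  expect_true(all(fg[d == 0] == 0))
  expect_equal(foreground(bg, img), fg)

  expect_error(foreground(bg, matrix(1, 10, 10)), "mismatch")
})

test_that("otsu binarization matches the oracle on a bimodal raster", {
  g <- matrix(c(rep(10 / 255, 90), rep(200 / 255, 10)), 10, 10)
  b <- binarize_otsu(g)
  expect_equal(sum(b), 10)
  expect_equal(which(b == 1), which(g > 100 / 255))

  # inverted contrast selects the complementary pixels
  b_inv <- binarize_otsu(1 - g)
  expect_equal(b_inv, 1 - b)

  # constant rasters have no foreground by convention
  expect_equal(binarize_otsu(matrix(0, 5, 5)), matrix(0, 5, 5))
  expect_equal(binarize_otsu(matrix(0.7, 5, 5)), matrix(0, 5, 5))
})

test_that("otsu threshold equals the exhaustive sweep oracle", {
  withr::with_seed(11, {
    for (i in 1:50) {
      n_levels <- sample(2:8, 1)
      vals <- sample(0:255, n_levels) / 255
      gray <- matrix(sample(vals, 400, replace = TRUE), 20, 20)
      expect_equal(otsu_threshold(gray), otsu_sweep_oracle(gray),
                   info = paste("histogram", i))
    }
  })
})

test_that("morphological cleanup removes specks and fills holes", {
  cfg <- seg_config(open_kernel = 3, close_kernel = 3)

  speck <- matrix(0, 30, 30)
  speck[15, 15] <- 1
  expect_equal(sum(morph_clean(speck, cfg)), 0)

  disk <- disk_raster(120, 120, 60, 60, 50)
  opened <- morph_clean(disk, seg_config(open_kernel = 3, close_kernel = 0))
  # open = erode then dilate, computed directly as the oracle
  k <- EBImage::makeBrush(3, "box")
  oracle <- EBImage::imageData(
    EBImage::dilate(EBImage::erode(EBImage::Image(disk), k), k)
  )
  expect_equal(opened, (oracle > 0) * 1)

  holey <- disk_raster(40, 40, 20, 20, 10)
  holey[20, 20] <- 0
  closed <- morph_clean(holey, seg_config(open_kernel = 0, close_kernel = 3))
  expect_equal(closed[20, 20], 1)
})

test_that("extract_detections reports one ordered detection per component", {
  expect_equal(nrow(extract_detections(matrix(0, 50, 50))), 0)

  img <- matrix(0, 200, 150)
  img <- pmax(img, disk_raster(200, 150, 40, 40, 12))
  img <- pmax(img, disk_raster(200, 150, 120, 40, 12))
  img <- pmax(img, disk_raster(200, 150, 80, 110, 12))
  det <- extract_detections(img, frame_index = 7,
                            config = seg_config(min_blob_area = 100))
  expect_equal(nrow(det), 3)
  expect_equal(det$frame_index, rep(7L, 3))
  # ordered by (y_min, x_min); disk bbox is [c - r, c + r] in 1-based pixels
  expect_equal(det$x_min, c(40 - 12 - 1, 120 - 12 - 1, 80 - 12 - 1))
  expect_equal(det$y_min, c(40 - 12 - 1, 40 - 12 - 1, 110 - 12 - 1))
  expect_equal(det$width, rep(25, 3))
  # centroid is the bbox center and lies inside the bbox
  expect_equal(det$cx, det$x_min + det$width / 2)
  expect_true(all(det$cx >= det$x_min & det$cx < det$x_min + det$width))

  # touching blobs merge into a single detection (known failure mode)
  merged <- pmax(disk_raster(100, 100, 40, 50, 15),
                 disk_raster(100, 100, 60, 50, 15))
  expect_equal(nrow(extract_detections(merged,
                                       config = seg_config(min_blob_area = 100))), 1)
})

test_that("segment_frame composes the stages and respects min_blob_area", {
  bg <- matrix(0.92, 300, 200)
  expect_equal(nrow(segment_frame(bg, bg)), 0)

  img <- bg
  big <- disk_raster(300, 200, 80, 100, 25)
  small <- disk_raster(300, 200, 220, 100, 6)
  img[big == 1] <- 0.2
  img[small == 1] <- 0.2
  det <- segment_frame(img, bg, config = small_seg_config())
  expect_equal(nrow(det), 1)  # the small blob falls under min_blob_area
  expect_true(abs(det$cx - 79) < 3 && abs(det$cy - 99) < 3)

  # composition equals running the stages by hand
  manual <- extract_detections(
    morph_clean(binarize_otsu(foreground(img, bg)), small_seg_config()),
    0L, small_seg_config()
  )
  expect_equal(det, manual)
})

test_that("segmentation of a generated scene recovers the planted insects", {
  cfg <- small_scene_config(n_insects = 3, n_frames = 2, seed = 21)
  scene <- generate_scene(cfg)
  bg <- scene_background(scene)
  det1 <- segment_frame(scene$frames[[1]], bg, 1, small_seg_config())
  expect_equal(nrow(det1), 3)
  # every detection is matched by a planted insect within a few pixels
  truth1 <- dplyr::filter(scene$truth, frame_index == 1)
  d <- sapply(seq_len(3), function(i) {
    min(sqrt((truth1$cx - det1$cx[i])^2 + (truth1$cy - det1$cy[i])^2))
  })
  expect_true(all(d < 4))

  # determinism: same inputs give identical detection tables
  expect_identical(det1,
                   segment_frame(scene$frames[[1]], bg, 1, small_seg_config()))
})

test_that("frame files order naturally and round-trip through CSV", {
  dir <- withr::local_tempdir()
  for (i in c(1, 2, 10, 21)) {
    EBImage::writeImage(EBImage::Image(matrix(0.5, 8, 8)),
                        file.path(dir, paste0("frame", i, ".png")))
  }
  files <- basename(mothtrap:::list_frame_files(dir))
  expect_equal(files, c("frame1.png", "frame2.png", "frame10.png", "frame21.png"))

  det <- make_detection(50, 60, 20, 22, 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_detections(det, path)
  expect_equal(as.data.frame(read_detections(path)), as.data.frame(det))
})
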