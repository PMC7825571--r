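test_that("parameter accounting reproduces the architecture ranking", {
  expect_equal(count_parameters(arch_spec(5, 3, 32, 64, 512)), 2197578)
  expect_equal(count_parameters(arch_spec(3, 3, 32, 128, 512)), 4330122)
  expect_equal(count_parameters(arch_spec(5, 1, 32, 128, 512)), 4266122)
  expect_equal(count_parameters(arch_spec(3, 3, 32, 64, 512)), 2196042)
  expect_equal(count_parameters(arch_spec(5, 3, 32, 128, 512)), 4331658)
  expect_equal(count_parameters(arch_spec(5, 1, 64, 64, 512)), 2185674)
  expect_equal(count_parameters(arch_spec(3, 3, 64, 64, 256)), 1163978)
  expect_equal(count_parameters(arch_spec(3, 3, 64, 64, 512)), 2215370)
})

test_that("allocated weights match the closed-form count across the grid", {
  grid <- enumerate_grid(optimizers = "adam")
  expect_equal(nrow(grid), 2 * 2 * 2 * 3 * 2)
  for (i in seq_len(nrow(grid))) {
    spec <- grid$spec[[i]]
    model <- build_model(spec, seed = 1)
    expect_identical(mothtrap:::model_parameter_total(model),
                     as.numeric(count_parameters(spec)),
                     info = paste(unlist(spec[1:5]), collapse = ","))
  }
})

test_that("the default grid contains the ranked architectures", {
  grid <- enumerate_grid()
  key <- with(grid, paste(kernel_first, kernel_last, depth_first, depth_last,
                          fc_size, optimizer))
  ranked <- c(
    "3 3 32 128 512", "5 1 32 128 512", "5 3 32 64 512", "3 3 32 64 512",
    "5 3 32 128 512", "5 1 64 64 512", "5 3 32 32 512", "5 3 64 128 512",
    "3 3 64 64 256", "3 3 64 64 512"
  )
  for (opt in c("adam", "sgd")) {
    expect_true(all(paste(ranked, opt) %in% key))
  }
  expect_equal(nrow(enumerate_grid(3, 3, 32, 64, 512, "adam")), 1)
})

test_that("hyperparameters outside the search space are rejected", {
  expect_error(arch_spec(kernel_first = 2), "kernel_first")
  expect_error(arch_spec(depth_last = 48), "depth_last")
  expect_error(arch_spec(fc_size = 128), "fc_size")
})

test_that("the flatten width follows the last convolution depth", {
  m64 <- build_model(arch_spec(5, 3, 32, 64, 512), seed = 1)
  expect_equal(nrow(m64$weights$W5), 4096)   # 8 * 8 * 64
  m128 <- build_model(arch_spec(3, 3, 32, 128, 512), seed = 1)
  expect_equal(nrow(m128$weights$W5), 8192)  # 8 * 8 * 128
})

test_that("prediction yields a softmax distribution even untrained", {
  model <- build_model(arch_spec(), seed = 2)
  crops <- generate_crop_dataset(n_classes = 3, n_per_class = 2, seed = 3)
  probs <- predict(model, crops, type = "prob")
  expect_equal(dim(probs), c(6, 10))
  expect_equal(rowSums(probs), rep(1, 6), tolerance = 1e-5)
  labs <- predict(model, crops)
  expect_true(all(labs$confidence > 0 & labs$confidence <= 1))
  expect_true(all(labs$label %in% moth_classes()))
  expect_error(predict(model, array(0, c(64, 64, 3))), "128x128x3")
})

test_that("crop preprocessing resizes, pads and respects frame bounds", {
  frame <- array(runif(600 * 500 * 3), c(600, 500, 3))
  det <- make_detection(300, 250, 368, 353)
  crop <- preprocess_crop(frame, det, pad_fraction = 0.1)
  expect_equal(dim(crop), c(128, 128, 3))
  expect_true(all(crop >= 0 & crop <= 1))

  # an exact-size bbox with no padding is returned pixel-identical
  det128 <- tibble::tibble(x_min = 100, y_min = 90, width = 128, height = 128)
  crop128 <- preprocess_crop(frame, det128, pad_fraction = 0)
  expect_equal(crop128, frame[101:228, 91:218, ])

  # a corner bbox with padding never reads out of bounds
  corner <- tibble::tibble(x_min = 0, y_min = 0, width = 60, height = 40)
  expect_no_error(preprocess_crop(frame, corner, pad_fraction = 0.1))

  expect_error(preprocess_crop(frame,
                               tibble::tibble(x_min = 5, y_min = 5,
                                              width = 0, height = 10)),
               "degenerate")
})

test_that("augmentation multiplies counts, preserves labels, is seeded", {
  crops <- generate_crop_dataset(n_classes = 3, n_per_class = 4, seed = 5,
                                 size = 32)
  one <- augment(crops, factor = 1, seed = 9)
  expect_identical(one$image, crops$image)  # identity copy

  aug <- augment(crops, factor = 5, seed = 9)
  expect_equal(nrow(aug), 60)
  expect_equal(as.vector(table(aug$class)), rep(20, 3))
  expect_equal(aug$class, rep(crops$class, each = 5))

  aug2 <- augment(crops, factor = 5, seed = 9)
  expect_identical(aug, aug2)
  aug3 <- augment(crops, factor = 5, seed = 10)
  expect_false(identical(aug, aug3))
})

test_that("training rejects degenerate inputs", {
  model <- build_model(arch_spec(), seed = 1)
  single <- generate_crop_dataset(n_classes = 2, n_per_class = 3, seed = 1)
  single <- dplyr::filter(single, class == single$class[1])
  expect_error(train_cnn(model, single), "two classes")
})

test_that("training on separable crops learns and reports coherently", {
  crops <- generate_crop_dataset(n_classes = 10, n_per_class = 12, seed = 13)
  model <- build_model(arch_spec(), seed = 13)
  cfg <- train_config(epochs = 5, seed = 13)
  fit <- train_cnn(model, crops, cfg)

  expect_true(fit$trained)
  expect_lt(dplyr::last(fit$history$loss), fit$history$loss[1])
  expect_gt(fit$validation$macro_f1, 0.25)

  # confusion-matrix row sums equal the per-class validation counts
  conf <- fit$validation$confusion
  val_n <- rowSums(conf)
  expect_equal(sum(val_n), fit$validation$n_val)
  expect_true(all(val_n[names(val_n) %in% as.character(crops$class)] >= 1))

  met <- tidy(fit)
  expect_equal(nrow(met), 10)
  g <- glance(fit)
  expect_equal(g$parameters, 2197578L)
  expect_equal(g$n_train + g$n_val, nrow(crops))

  # a fixed seed makes the whole fit reproducible
  refit <- train_cnn(build_model(arch_spec(), seed = 13), crops, cfg)
  expect_equal(refit$validation$macro_f1, fit$validation$macro_f1)
  expect_identical(refit$weights$W6, fit$weights$W6)

  # the trained model round-trips through its weights file
  path <- withr::local_tempfile(fileext = ".rds")
  write_model(fit, path)
  expect_equal(read_model(path)$weights, fit$weights)
})
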