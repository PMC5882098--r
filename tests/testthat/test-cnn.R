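# The fully-convolutional classifier: parameter accounting, training
# behavior, dense maps and aggregation.

test_that("parameter counts follow the closed-form layer sums", {
  # single 3x3 conv 3 -> 16, bias-free, with BN: 3*3*3*16 + 2*16 = 464
  single <- list(W1 = matrix(0, 16, 27), gamma1 = rep(1, 16),
                 beta1 = rep(0, 16), rmean1 = rep(0, 16), rvar1 = rep(1, 16))
  expect_equal(count_parameters(single), 464)
  expect_equal(count_parameters(list()), 0)
  # reference layout: hand sum of conv + BN + head terms
  hand <- (3 * 3 * 3 * 16 + 32) + (3 * 3 * 16 * 16 + 32) +
    (3 * 3 * 16 * 24 + 48) + (3 * 3 * 24 * 30 + 60) + (4 * 4 * 30 * 2 + 2)
  model <- build_cnn(rng_seed = 1)
  expect_equal(count_parameters(model), hand)
  expect_gte(count_parameters(model), 12800)
  expect_lte(count_parameters(model), 14200)
})

test_that("architectures that exhaust the spatial extent are rejected", {
  too_deep <- replicate(6, list(kernel = 3, out_channels = 8, bn = TRUE,
                                relu = TRUE, pool = TRUE), simplify = FALSE)
  expect_error(cnn_architecture(stages = too_deep),
               class = "hf_invalid_architecture")
})

test_that("initialization is deterministic in the seed", {
  expect_identical(build_cnn(rng_seed = 5)$params, build_cnn(rng_seed = 5)$params)
  expect_false(identical(build_cnn(rng_seed = 5)$params,
                         build_cnn(rng_seed = 6)$params))
})

test_that("training rejects single-class or mis-sized patch sets", {
  ps <- separable_patches(20)
  one_class <- ps
  one_class$meta$label <- "failing"
  m <- build_cnn(rng_seed = 1)
  expect_error(train_cnn(m, one_class), class = "hf_invalid_data")
  small <- hfhisto:::patch_set(array(as.raw(0), c(32, 32, 3, 4)),
                               data.frame(patient_id = "x", roi_id = "x",
                                          row = 0L, col = 0L, orientation = 0L,
                                          label = c("failing", "failing",
                                                    "non_failing", "non_failing")),
                               32L)
  expect_error(train_cnn(m, small), class = "hf_invalid_argument")
})

test_that("a separable patch set is learned to perfect accuracy within 10 epochs", {
  ps <- separable_patches(100)
  m <- train_cnn(build_cnn(rng_seed = 1), ps,
                 config = training_config(epochs = 10, rng_seed = 2))
  expect_equal(nrow(m$log), 10)
  expect_equal(max(m$log$train_acc), 1)
  pr <- predict(m, ps)
  expect_equal(mean((pr > 0.5) == (ps$meta$label == "failing")), 1)
})

test_that("repeated passes over one mini-batch keep improving the best loss", {
  ps <- separable_patches(32)  # exactly one 64-patch batch
  m <- train_cnn(build_cnn(rng_seed = 3), ps,
                 config = training_config(epochs = 50, batch_size = 64,
                                          rng_seed = 4))
  best_so_far <- cummin(m$log$loss)
  expect_true(all(diff(best_so_far) <= 0))
  expect_lt(best_so_far[50], m$log$loss[1])
})

test_that("default training runs 30 epochs at batch size 64", {
  cfg <- training_config()
  expect_equal(cfg$epochs, 30)
  expect_equal(cfg$batch_size, 64)
  expect_equal(cfg$optimizer, "sgd")
  ps <- separable_patches(40)
  m <- train_cnn(build_cnn(rng_seed = 1), ps, config = training_config(rng_seed = 5))
  expect_equal(m$log$epoch, 1:30)
})

test_that("training is deterministic under fixed seeds and data", {
  ps <- separable_patches(48)
  cfg <- training_config(epochs = 4, rng_seed = 11)
  m1 <- train_cnn(build_cnn(rng_seed = 9), ps, config = cfg)
  m2 <- train_cnn(build_cnn(rng_seed = 9), ps, config = cfg)
  expect_identical(m1$log$loss, m2$log$loss)
  expect_identical(m1$params, m2$params)
})

test_that("a 64-px input yields a single map pixel and normalized channel scores", {
  m <- build_cnn(rng_seed = 2)
  roi64 <- region_of_interest(
    generate_tissue_image(tissue_params(0.3, rng_seed = 1), 128)[1:64, 1:64, ,
                                                                 drop = FALSE],
    "P", "r64")
  map <- predict_probability_map(m, roi64)
  expect_equal(dim(map$values), c(1L, 1L))
  expect_equal(map$downsample_factor, 8L)
  roi <- region_of_interest(generate_tissue_image(tissue_params(0.3, rng_seed = 1), 160),
                            "P", "r160")
  big <- predict_probability_map(m, roi)
  expect_true(all(big$values >= 0 & big$values <= 1))
  # two-channel scores sum to 1 everywhere: the non-failing map is 1 - map
  raw_arr <- array(as.raw(roi$pixels), dim = c(dim(roi$pixels), 1L))
  out <- hfhisto:::cnn_infer(m, raw_arr)
  expect_equal(colSums(out$probs), rep(1, ncol(out$probs)), tolerance = 1e-5)
  tiny <- region_of_interest(roi$pixels[1:48, 1:48, , drop = FALSE], "P", "r48")
  expect_error(predict_probability_map(m, tiny), class = "hf_invalid_argument")
})

test_that("the dense map equals per-crop probabilities at random locations", {
  m <- build_cnn(rng_seed = 4)
  roi <- region_of_interest(generate_tissue_image(tissue_params(0.35, rng_seed = 6), 160),
                            "P", "r")
  map <- predict_probability_map(m, roi)
  stride <- map$downsample_factor
  withr::with_seed(10, {
    for (trial in 1:10) {
      i <- sample(nrow(map$values), 1)
      j <- sample(ncol(map$values), 1)
      r0 <- (i - 1) * stride
      c0 <- (j - 1) * stride
      crop <- region_of_interest(
        roi$pixels[(r0 + 1):(r0 + 64), (c0 + 1):(c0 + 64), , drop = FALSE],
        "P", "crop")
      expect_equal(map$values[i, j],
                   predict_probability_map(m, crop)$values[1, 1],
                   tolerance = 1e-4)
    }
  })
})

test_that("image probability is the arithmetic mean of the map", {
  expect_equal(image_probability(matrix(0.7, 5, 5)), 0.7)
  expect_equal(image_probability(matrix(c(0, 1), 10, 10)), 0.5)
  withr::with_seed(2, {
    v <- matrix(runif(36), 6, 6)
    p <- image_probability(v)
    expect_gte(p, min(v)); expect_lte(p, max(v))
  })
  expect_error(image_probability(matrix(numeric(0), 0, 0)),
               class = "hf_degenerate_input")
})

test_that("checkpoints round-trip through save and load", {
  m <- build_cnn(rng_seed = 1)
  path <- withr::local_tempfile(fileext = ".rds")
  save_cnn(m, path)
  m2 <- load_cnn(path)
  expect_identical(m$params, m2$params)
})
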