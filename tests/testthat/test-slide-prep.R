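# Tissue masking and ROI sampling.

test_that("area-averaging downsampling scales dimensions and conserves constants", {
  px <- array(as.integer(77), c(400, 400, 3))
  sl <- slide_image(px, mpp = 0.5)
  out <- downsample_to_target(sl, 2.0)
  expect_equal(dim(out$pixels)[1:2], c(100L, 100L))
  expect_equal(out$mpp, 2.0)
  expect_true(all(out$pixels == 77L))
  expect_identical(downsample_to_target(sl, 0.5), sl)
  expect_error(downsample_to_target(sl, 0.25), class = "hf_invalid_argument")
})

test_that("the Otsu threshold matches the exhaustive between-class-variance argmax", {
  counts <- integer(256); counts[11] <- 500; counts[201] <- 500
  expect_equal(otsu_threshold(counts), otsu_brute_force(counts))
  expect_error(otsu_threshold(c(rep(0, 100), 1000, rep(0, 155))),
               class = "hf_degenerate_input")
  withr::with_seed(42, {
    for (i in 1:50) {
      h <- as.integer(rpois(256, lambda = runif(1, 0.5, 30)))
      if (sum(h > 0) < 2) h[c(3, 250)] <- h[c(3, 250)] + 5L
      expect_equal(otsu_threshold(h), otsu_brute_force(h))
    }
  })
})

test_that("tissue masks recover the generated tissue extent", {
  sl <- generate_slide(tissue_params(0.1, rng_seed = 2), canvas_px = 600,
                       tissue_extent_px = 400, rng_seed = 3)
  mask <- compute_tissue_mask(sl)
  expect_equal(dim(mask$mask), dim(sl$pixels)[1:2])
  expect_lt(abs(sum(mask$mask) - 400^2) / 400^2, 0.10)
  expect_true(mask$threshold_used >= 0 && mask$threshold_used <= 255)
  expect_equal(mask$provenance, "otsu")
  const <- slide_image(array(100L, c(64, 64, 3)), mpp = 2)
  expect_error(compute_tissue_mask(const), class = "hf_degenerate_input")
})

test_that("mask refinement applies edit layers and tracks provenance", {
  sl <- toy_slide(64)
  m0 <- full_mask(sl)
  m0$mask[1:32, ] <- FALSE
  r0 <- refine_mask(m0)
  expect_equal(r0$mask, m0$mask)
  expect_equal(r0$provenance, "otsu+manual")
  add <- matrix(FALSE, 64, 64); add[1:10, 1:10] <- TRUE
  r1 <- refine_mask(m0, additions = add)
  expect_equal(sum(r1$mask), sum(m0$mask) + 100)
  rem <- matrix(TRUE, 64, 64)
  expect_error(refine_mask(m0, removals = rem), class = "hf_degenerate_input")
  expect_error(refine_mask(m0, additions = matrix(FALSE, 10, 10)),
               class = "hf_invalid_argument")
})

test_that("ROI sampling honors counts, bounds and the tissue fraction", {
  sl <- generate_slide(tissue_params(0.1, rng_seed = 2), canvas_px = 640,
                       tissue_extent_px = 560, rng_seed = 3)
  mask <- compute_tissue_mask(sl)
  rois <- sample_rois(sl, mask, side_px = 96, rng_seed = 1)  # default n = 11
  expect_length(rois, 11)
  one <- sample_rois(toy_slide(128), full_mask(toy_slide(128)), n = 1,
                     side_px = 64, rng_seed = 2)
  expect_length(one, 1)
  expect_true(one[[1]]$row >= 0 && one[[1]]$row + 64 <= 128)
})

test_that("an overfull request raises a capacity error naming the placed count", {
  sl <- toy_slide(130)  # fits at most 4 non-overlapping 64-px squares
  err <- tryCatch(
    sample_rois(sl, full_mask(sl), n = 11, side_px = 64, rng_seed = 1,
                max_attempts = 3000),
    hf_capacity_error = function(e) e)
  expect_s3_class(err, "hf_capacity_error")
  expect_lte(err$placed, 4)
  expect_match(conditionMessage(err), as.character(err$placed))
})

test_that("sampled ROIs never overlap and all meet the tissue bound", {
  sl <- generate_slide(tissue_params(0.15, rng_seed = 7), canvas_px = 512,
                       tissue_extent_px = 420, rng_seed = 8)
  mask <- compute_tissue_mask(sl)
  for (seed in 1:100) {
    rois <- sample_rois(sl, mask, n = 5, side_px = 64,
                        min_tissue_fraction = 0.9, rng_seed = seed)
    coords <- t(vapply(rois, function(r) c(r$row, r$col), c(0, 0)))
    for (i in 1:4) for (j in (i + 1):5) {
      expect_false(abs(coords[i, 1] - coords[j, 1]) < 64 &&
                     abs(coords[i, 2] - coords[j, 2]) < 64)
    }
    for (r in rois) {
      frac <- mean(mask$mask[(r$row + 1):(r$row + 64), (r$col + 1):(r$col + 64)])
      expect_gte(frac, 0.9)
    }
  }
  a <- sample_rois(sl, mask, n = 5, side_px = 64, rng_seed = 33)
  b <- sample_rois(sl, mask, n = 5, side_px = 64, rng_seed = 33)
  expect_identical(lapply(a, function(r) c(r$row, r$col)),
                   lapply(b, function(r) c(r$row, r$col)))
})
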