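# Engineered feature bank, mRMR selection and the random-forest stage.

test_that("degenerate textures produce degenerate features", {
  const <- region_of_interest(array(100L, c(128, 128, 3)), "P", "c")
  f <- extract_features(const)
  expect_length(f, 333)
  expect_true(all(abs(f[grep("(_sd$|_skew$|_kurtosis$)", names(f))]) < 1e-8))
  # LBP mass concentrates in a single bin on a flat image
  lbp <- f[grep("^gray_lbp", names(f))]
  expect_equal(max(lbp), 1)
  expect_error(extract_features(region_of_interest(array(1L, c(64, 64, 3)),
                                                   "P", "x")$pixels),
               class = "hf_invalid_argument")
})

test_that("co-occurrence contrast separates a checkerboard from a flat image", {
  side <- 64
  cb <- outer(1:side, 1:side, function(i, j) ((i + j) %% 2) * 255L)
  cb_roi <- region_of_interest(array(rep(cb, 3), c(side, side, 3)), "P", "cb")
  flat <- region_of_interest(array(120L, c(side, side, 3)), "P", "fl")
  f_cb <- extract_features(cb_roi)
  f_fl <- extract_features(flat)
  expect_gt(f_cb["gray_har_contrast"], f_fl["gray_har_contrast"])
  # hand check on the 2-level co-occurrence of a checkerboard: every
  # horizontal neighbour pair alternates, so the contrast is maximal
  board <- outer(1:4, 1:4, function(i, j) ((i + j) %% 2L) + 1L)
  P <- hfhisto:::glcm(board, 2L, 0L, 1L)
  expect_equal(unname(hfhisto:::haralick_stats(P)["contrast"]), 1)
})

test_that("feature extraction is bit-deterministic", {
  roi <- region_of_interest(generate_tissue_image(tissue_params(0.3, rng_seed = 2), 144),
                            "P", "r")
  expect_identical(extract_features(roi), extract_features(roi))
})

test_that("mRMR selection obeys its greedy definition", {
  withr::with_seed(5, {
    X <- matrix(rnorm(300 * 8), 300, 8)
    y <- rep(c("a", "b"), each = 150)
    X[, 3] <- X[, 3] + 2.5 * (y == "a")
    X[, 6] <- X[, 3] + rnorm(300, sd = 0.01)  # duplicate informative feature
  })
  s1 <- mrmr_select(X, y, k = 1)
  rel <- sapply(seq_len(ncol(X)), function(j)
    hfhisto:::mutual_information(hfhisto:::discretize_terciles(X[, j]),
                                 as.integer(factor(y))))
  expect_equal(s1$indices, which.max(rel))
  s2 <- mrmr_select(X, y, k = 2)
  expect_true(3 %in% s2$indices || 6 %in% s2$indices)
  expect_false(all(c(3, 6) %in% s2$indices))  # redundancy penalized
  expect_equal(s2$indices, mrmr_brute_force(X, y, 2))
  expect_error(mrmr_select(X, rep("a", 300), k = 2), class = "hf_invalid_data")
  # default k
  expect_equal(eval(formals(mrmr_select)$k), 20)
})

test_that("mRMR equals exhaustive greedy enumeration on small problems", {
  withr::with_seed(31, {
    for (trial in 1:20) {
      p <- sample(3:6, 1)
      n <- 120
      X <- matrix(rnorm(n * p), n, p)
      y <- rep(c("a", "b"), length.out = n)
      ninf <- sample(1:p, 1)
      for (j in sample(p, ninf)) X[, j] <- X[, j] + runif(1, 0.5, 3) * (y == "a")
      k <- sample(2:p, 1)
      expect_equal(mrmr_select(X, y, k = k)$indices, mrmr_brute_force(X, y, k))
    }
  })
})

test_that("the forest stage is a seeded 1000-tree bagged ensemble", {
  withr::with_seed(9, {
    X <- matrix(rnorm(80 * 5), 80, 5)
    y <- rep(c("failing", "non_failing"), each = 40)
    X[, 2] <- X[, 2] + 4 * (y == "failing")  # linearly separable
  })
  fit <- train_rf(X[1:60, ], y[1:60], rng_seed = 1)
  expect_equal(fit$ntree, 1000)
  held <- stats::predict(fit, X[61:80, ])
  expect_equal(mean(held == y[61:80]), 1)
  fit2 <- train_rf(X[1:60, ], y[1:60], rng_seed = 1)
  expect_identical(stats::predict(fit, X[61:80, ], type = "vote"),
                   stats::predict(fit2, X[61:80, ], type = "vote"))
  expect_error(train_rf(X, rep("failing", 80)), class = "hf_invalid_data")
})

test_that("forest probabilities are vote fractions", {
  withr::with_seed(10, {
    X <- matrix(rnorm(60 * 4), 60, 4)
    y <- rep(c("failing", "non_failing"), each = 30)
    X[, 1] <- X[, 1] + 5 * (y == "failing")
  })
  model <- fit_charm(X, y, k = 3, n_trees = 200, rng_seed = 2)
  pr <- rf_predict(model, X)
  expect_true(all(pr >= 0 & pr <= 1))
  # on a separable class nearly every tree votes failing
  expect_true(all(pr[y == "failing"] > 0.85))
  expect_gt(mean(pr[y == "failing"]), 0.95)
  # failing + non-failing vote fractions sum to one
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  votes <- stats::predict(model$forest, Z[, model$selection$indices],
                          type = "vote")
  expect_equal(unname(rowSums(votes)), rep(1, nrow(votes)))
  expect_error(rf_predict(model, X[, 1:2]), class = "hf_invalid_argument")
})

test_that("test-set standardization reuses training statistics exactly", {
  withr::with_seed(12, {
    X <- matrix(rnorm(50 * 4), 50, 4)
    y <- rep(c("failing", "non_failing"), 25)
    X[, 1] <- X[, 1] + 3 * (y == "failing")
  })
  model <- fit_charm(X, y, k = 2, n_trees = 100, rng_seed = 3)
  expect_equal(model$center, colMeans(X))
  shifted <- X + 100  # a shifted test set must be judged on the training scale
  pr_orig <- rf_predict(model, X)
  pr_shift <- rf_predict(model, shifted)
  expect_false(isTRUE(all.equal(pr_orig, pr_shift)))
})
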