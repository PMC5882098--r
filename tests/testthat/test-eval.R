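# Aggregation thresholds, metrics, statistical comparisons and patient-level
# splits.

test_that("the image call is strict at the threshold", {
  expect_true(image_prediction(0.51))
  expect_false(image_prediction(0.50))
  expect_false(image_prediction(0))
  expect_true(image_prediction(1))
  grid <- seq(0, 1, by = 0.01)
  calls <- image_prediction(grid)
  expect_equal(sum(diff(calls) != 0), 1)       # exactly one flip
  expect_equal(grid[which(diff(calls) != 0) + 1], 0.51)
  expect_error(image_prediction(1.2), class = "hf_invalid_argument")
})

test_that("patient probability is the order-invariant mean of image calls", {
  calls <- c(rep(TRUE, 6), rep(FALSE, 5))
  expect_equal(patient_probability(calls), 6 / 11)
  expect_equal(patient_probability(rep(TRUE, 11)), 1)
  withr::with_seed(1, {
    for (i in 1:10)
      expect_equal(patient_probability(sample(calls)), 6 / 11)
  })
  expect_error(patient_probability(logical(0)), class = "hf_degenerate_input")
})

test_that("patient diagnosis is the strict majority vote", {
  expect_true(patient_diagnosis(6 / 11))
  expect_false(patient_diagnosis(5 / 11))
  expect_false(patient_diagnosis(0.5))  # exact tie -> non-failing
  # exhaustive agreement with direct majority counting on 5 images
  for (pattern in 0:31) {
    calls <- as.logical(bitwAnd(pattern, 2^(0:4)) > 0)
    expect_equal(patient_diagnosis(mean(calls)), sum(calls) > 2.5)
  }
})

test_that("confusion metrics match hand arithmetic and behave at the null", {
  calls <- rep(c(TRUE, FALSE, FALSE, TRUE), c(8, 2, 9, 1))
  truth <- rep(c(TRUE, TRUE, FALSE, FALSE), c(8, 2, 9, 1))
  m <- confusion_metrics(calls, truth)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.9)
  expect_equal(m$accuracy, 0.85)
  expect_equal(m$ppv, 8 / 9)
  perfect <- confusion_metrics(truth, truth)
  expect_equal(c(perfect$accuracy, perfect$sensitivity, perfect$specificity,
                 perfect$ppv), rep(1, 4))
  withr::with_seed(8, {
    n <- 10000
    r <- confusion_metrics(sample(c(TRUE, FALSE), n, TRUE),
                           sample(c(TRUE, FALSE), n, TRUE))
    expect_lt(abs(r$accuracy - 0.5), 3 * sqrt(0.25 / n))
  })
  expect_warning(res <- confusion_metrics(c(FALSE, FALSE), c(TRUE, FALSE)),
                 "positive predictive")
  expect_true(is.na(res$ppv))
  expect_error(confusion_metrics(TRUE, c(TRUE, FALSE)),
               class = "hf_invalid_argument")
})

test_that("the ROC area equals the tie-corrected rank statistic", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.1), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), class = "hf_invalid_data")
  withr::with_seed(14, {
    for (i in 1:100) {
      n <- sample(20:200, 1)
      scores <- sample(seq(0, 1, by = 0.05), n, TRUE)  # heavy ties
      truth <- sample(c(TRUE, FALSE), n, TRUE)
      if (all(truth) || !any(truth)) truth[1:2] <- c(TRUE, FALSE)
      expect_equal(roc_auc(scores, truth)$auc, auc_rank_oracle(scores, truth),
                   tolerance = 1e-12)
    }
  })
})

test_that("ROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(3, {
    scores <- runif(60)
    truth <- sample(c(TRUE, FALSE), 60, TRUE)
  })
  ours <- roc_auc(scores, truth)$auc
  ref <- suppressMessages(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                              levels = c(FALSE, TRUE),
                                              direction = "<")))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
})

test_that("Cohen's kappa matches hand computation and the independence null", {
  a <- rep(c("x", "x", "y", "y"), c(20, 5, 10, 15))
  b <- rep(c("x", "y", "x", "y"), c(20, 5, 10, 15))
  expect_equal(cohens_kappa(a, b), 0.4)
  expect_equal(cohens_kappa(c("x", "y", "x"), c("x", "y", "x")), 1)
  withr::with_seed(4, {
    n <- 10000
    ra <- sample(c("x", "y"), n, TRUE)
    rb <- sample(c("x", "y"), n, TRUE)
    # sd of kappa under independence with balanced marginals ~ 1/sqrt(n)
    expect_lt(abs(cohens_kappa(ra, rb)), 3 / sqrt(n))
  })
  expect_error(cohens_kappa(rep("x", 5), rep("x", 5)),
               class = "hf_degenerate_input")
})

test_that("t statistics match hand computation and stats::t.test", {
  a <- c(0.95, 0.96, 0.97); b <- c(0.86, 0.87, 0.88)
  r <- unpaired_ttest(a, b)
  expect_equal(r$t, 0.09 / (0.01 * sqrt(2 / 3)), tolerance = 1e-10)
  expect_equal(r$df, 4)
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(r$t, unname(ref$statistic))
  expect_equal(r$p, ref$p.value)
  ident <- unpaired_ttest(a, a)
  expect_equal(c(ident$t, ident$p), c(0, 1))
  sw <- unpaired_ttest(b, a)
  expect_equal(sw$t, -r$t)
  expect_equal(sw$p, r$p)

  o <- one_sample_ttest(c(0.94, 0.97, 0.91), 0.75)
  expect_equal(o$t, (0.94 - 0.75) / (0.03 / sqrt(3)), tolerance = 1e-10)
  expect_equal(o$df, 2)
  expect_equal(one_sample_ttest(a, mean(a))$p, 1)
  refs <- seq(0.80, 0.30, by = -0.1)
  ps <- vapply(refs, function(mu) one_sample_ttest(a, mu)$p, 0)
  expect_true(all(diff(ps) < 0))  # p shrinks as the reference moves away
})

test_that("the KS comparison matches the brute-force ECDF sup difference", {
  same <- ks_compare(1:10, 1:10)
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  expect_equal(ks_compare(rep(0, 100), rep(1, 100))$D, 1)
  withr::with_seed(6, {
    a <- rnorm(17); b <- rnorm(23, mean = 0.6)
  })
  grid <- sort(c(a, b))
  d_brute <- max(abs(vapply(grid, function(t) mean(a <= t) - mean(b <= t), 0)))
  expect_equal(ks_compare(a, b)$D, d_brute, tolerance = 1e-12)
  ra <- roc_auc(c(a, b), rep(c(TRUE, FALSE), c(17, 23)))
  expect_silent(ks_compare_roc(ra, ra))
  expect_equal(ks_compare_roc(ra, ra)$D, 0)
  expect_error(ks_compare(numeric(0), 1:3), class = "hf_invalid_argument")
})

test_that("patient-level folds are stratified partitions", {
  pats <- data.frame(patient_id = sprintf("P%03d", 1:104),
                     label_v1 = rep(c("failing", "non_failing"), c(47, 57)),
                     label_v2 = "x", stringsAsFactors = FALSE)
  fold <- crossval_split(pats, n_folds = 3, rng_seed = 2)
  expect_equal(sort(as.integer(table(fold))), c(34L, 35L, 35L))
  expect_setequal(names(fold), pats$patient_id)
  per_label <- table(fold, pats$label_v1[match(names(fold), pats$patient_id)])
  expect_lte(diff(range(per_label[, "failing"])), 1)
  expect_lte(diff(range(per_label[, "non_failing"])), 1)
  expect_identical(fold, crossval_split(pats, n_folds = 3, rng_seed = 2))
  expect_error(crossval_split(pats[1:2, ], n_folds = 3),
               class = "hf_invalid_argument")
})

test_that("the train/test split reproduces the cohort design and never leaks", {
  pats <- data.frame(patient_id = sprintf("P%03d", 1:209),
                     label_v1 = rep(c("failing", "non_failing"), c(94, 115)),
                     label_v2 = "x", stringsAsFactors = FALSE)
  sp <- train_test_split(pats, rng_seed = 1)
  expect_length(sp$train, 104)
  expect_length(sp$test, 105)
  expect_length(intersect(sp$train, sp$test), 0)
  small <- data.frame(patient_id = sprintf("P%02d", 1:10),
                      label_v1 = rep(c("failing", "non_failing"), 5),
                      label_v2 = "x", stringsAsFactors = FALSE)
  ssp <- train_test_split(small, rng_seed = 3)
  expect_length(ssp$train, 5)
  lab <- small$label_v1[match(ssp$train, small$patient_id)]
  expect_lte(abs(sum(lab == "failing") - sum(lab == "non_failing")), 1)
})

test_that("aggregated patient records satisfy the aggregation identities", {
  withr::with_seed(5, {
    probs <- runif(33)
    pids <- rep(sprintf("P%02d", 1:3), each = 11)
    labels <- stats::setNames(c("failing", "non_failing", "failing"),
                              sprintf("P%02d", 1:3))
  })
  recs <- aggregate_patients(probs, pids, labels)
  for (i in seq_len(nrow(recs))) {
    calls <- image_prediction(probs[pids == recs$patient_id[i]])
    expect_equal(recs$patient_prob[i], mean(calls))
    expect_equal(recs$diagnosis[i], recs$patient_prob[i] > 0.5)
    expect_equal(recs$n_images[i], 11L)
  }
})
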