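# Consensus clustering: matrix semantics, CDF geometry, k selection and
# discordant-patient flagging.

test_that("well-separated clouds give an all-or-nothing consensus", {
  g <- generate_feature_clusters(2, 15, 20, 5, rng_seed = 1)
  cons <- consensus_cluster(g$features, k_range = 2, n_resamples = 50,
                            rng_seed = 2)
  M <- cons$matrices[["2"]]
  same <- outer(g$assignments, g$assignments, `==`)
  expect_true(all(M[same] == 1, na.rm = TRUE))
  expect_true(all(M[!same] == 0, na.rm = TRUE))
})

test_that("a single full-fraction resample reduces to plain co-membership", {
  g <- generate_feature_clusters(3, 8, 10, 5, rng_seed = 4)
  cons <- consensus_cluster(g$features, k_range = 3, n_resamples = 1,
                            item_fraction = 1, rng_seed = 5)
  M <- cons$matrices[["3"]]
  expect_true(all(M %in% c(0, 1)))
  sds <- apply(g$features, 2, sd)
  Z <- scale(g$features, scale = sds)
  ct <- stats::cutree(stats::hclust(dist(Z), "average"), 3)
  expect_equal(M, outer(ct, ct, function(a, b) (a == b) * 1),
               ignore_attr = TRUE)
})

test_that("consensus matrices equal the brute-force co-membership counts", {
  for (seed in c(3, 9)) {
    g <- generate_feature_clusters(2, 12, 6, 4, rng_seed = seed)
    cons <- consensus_cluster(g$features, k_range = 2:4, n_resamples = 20,
                              item_fraction = 0.75, rng_seed = seed + 50)
    brute <- consensus_brute_force(g$features, 2:4, 20, 0.75, seed + 50)
    for (ki in 1:3)
      expect_equal(unname(cons$matrices[[ki]]), unname(brute[[ki]]))
  }
})

test_that("consensus matrices are symmetric with unit diagonal and [0,1] entries", {
  g <- generate_feature_clusters(3, 10, 8, 5, rng_seed = 6)
  cons <- consensus_cluster(g$features, k_range = 2:5, n_resamples = 30,
                            rng_seed = 7)
  for (M in cons$matrices) {
    expect_equal(M, t(M))
    expect_true(all(diag(M) == 1))
    expect_true(all(M >= 0 & M <= 1, na.rm = TRUE))
  }
  expect_error(consensus_cluster(g$features, k_range = c(2, 40)),
               class = "hf_invalid_argument")
})

test_that("the consensus CDF has the closed-form geometry on ideal input", {
  g <- generate_feature_clusters(2, 15, 20, 5, rng_seed = 1)
  cons <- consensus_cluster(g$features, k_range = 2:3, n_resamples = 50,
                            rng_seed = 2)
  cc <- consensus_cdf(cons)
  M <- cons$matrices[["2"]]
  v <- M[upper.tri(M)]
  expect_equal(cc$area[["2"]], mean(v == 0, na.rm = TRUE), tolerance = 2e-3)
  # degenerate all-ones consensus (single-cluster-like): area ~ 0
  fake <- cons
  fake$matrices <- list(`2` = matrix(1, 10, 10), `3` = matrix(1, 10, 10))
  fake$k_range <- 2:3
  expect_lt(consensus_cdf(fake)$area[["2"]], 1e-3)
  # areas never decrease in k on a fixed dataset
  g2 <- generate_feature_clusters(3, 12, 6, 5, rng_seed = 8)
  cons2 <- consensus_cluster(g2$features, k_range = 2:6, n_resamples = 50,
                             rng_seed = 9)
  expect_true(all(diff(consensus_cdf(cons2)$area) >= -1e-9))
})

test_that("the selected cluster number recovers planted structure", {
  g3 <- generate_feature_clusters(3, 30, 8, 5, rng_seed = 1)
  cons3 <- consensus_cluster(g3$features, k_range = 2:6, n_resamples = 200,
                             rng_seed = 11)
  expect_equal(select_k(cons3), 3)
  g2 <- generate_feature_clusters(2, 30, 8, 5, rng_seed = 1)
  cons2 <- consensus_cluster(g2$features, k_range = 2:6, n_resamples = 200,
                             rng_seed = 11)
  expect_equal(select_k(cons2), 2)
  g1 <- generate_feature_clusters(1, 60, 0, 5, rng_seed = 1)
  cons1 <- consensus_cluster(g1$features, k_range = 2:6, n_resamples = 200,
                             rng_seed = 11)
  expect_equal(select_k(cons1), 2)  # k_min: no stable structure beyond it
})

test_that("discordant patients are flagged from cluster concentration", {
  # emulate image-level features: failing patients, non-failing patients, and
  # two occult patients whose images form an intermediate third component
  g <- generate_feature_clusters(3, 24, 10, 6, rng_seed = 13)
  pats <- c(rep(sprintf("F%02d", 1:4), each = 6),
            rep(sprintf("N%02d", 1:4), each = 6),
            rep(c("O01", "O02"), each = 12))
  labels <- stats::setNames(
    c(rep("failing", 4), rep("non_failing", 6)),
    c(sprintf("F%02d", 1:4), sprintf("N%02d", 1:4), "O01", "O02"))
  cons <- consensus_cluster(g$features, k_range = 2:5, n_resamples = 100,
                            rng_seed = 14, item_patients = pats)
  expect_equal(select_k(cons), 3)
  flagged <- flag_discordant_patients(cons, labels)
  expect_equal(flagged, c("O01", "O02"))
  # flagging is invariant to item order
  perm <- withr::with_seed(15, sample(nrow(g$features)))
  cons_p <- consensus_cluster(g$features[perm, ], k_range = 2:5,
                              n_resamples = 100, rng_seed = 14,
                              item_patients = pats[perm])
  expect_equal(flag_discordant_patients(cons_p, labels), c("O01", "O02"))
})

test_that("no patients are flagged in a clean two-class cohort", {
  g <- generate_feature_clusters(2, 24, 10, 6, rng_seed = 16)
  pats <- c(rep(sprintf("F%02d", 1:4), each = 6), rep(sprintf("N%02d", 1:4), each = 6))
  labels <- stats::setNames(c(rep("failing", 4), rep("non_failing", 4)),
                            c(sprintf("F%02d", 1:4), sprintf("N%02d", 1:4)))
  cons <- consensus_cluster(g$features, k_range = 2:5, n_resamples = 100,
                            rng_seed = 17, item_patients = pats)
  expect_equal(select_k(cons), 2)
  expect_length(flag_discordant_patients(cons, labels), 0)
})
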