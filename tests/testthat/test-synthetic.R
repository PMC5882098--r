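# Synthetic histology generator: rendering contracts, cohort bookkeeping and
# the clustering fixture.

test_that("tissue parameter validation rejects out-of-range values", {
  expect_error(tissue_params(fibrosis_fraction = 1.2), class = "hf_invalid_argument")
  expect_error(tissue_params(nucleus_scale = 0.5), class = "hf_invalid_argument")
  expect_error(tissue_params(fiber_disruption = -0.1), class = "hf_invalid_argument")
  p <- tissue_params(0.3, rng_seed = 1)
  expect_error(generate_tissue_image(p, side_px = 0), class = "hf_invalid_argument")
  expect_error(generate_tissue_image(p, side_px = 200, mpp = -1), class = "hf_invalid_argument")
  expect_error(generate_tissue_image(p, side_px = 100), class = "hf_invalid_argument")
})

test_that("rendered stroma fraction tracks the requested fibrosis fraction", {
  img0 <- generate_tissue_image(tissue_params(0, rng_seed = 3), side_px = 192)
  expect_lt(measured_stroma_fraction(img0), 0.05)  # perivascular only
  img4 <- generate_tissue_image(tissue_params(0.4, rng_seed = 1), side_px = 192)
  expect_lt(abs(measured_stroma_fraction(img4) - 0.40), 0.05)
})

test_that("rendering is a pure function of parameters and seed", {
  p <- tissue_params(0.25, rng_seed = 11)
  expect_identical(generate_tissue_image(p, 128), generate_tissue_image(p, 128))
})

test_that("failing and non-failing presets are distinguishable", {
  pre <- tissue_presets("strong")
  mk <- function(m) generate_tissue_image(
    tissue_params(m$fibrosis_fraction, m$nucleus_density, m$nucleus_scale,
                  m$fiber_disruption, rng_seed = 1), 128)
  h <- function(img) {
    counts <- lapply(1:3, function(ch) tabulate(img[, , ch] %/% 8 + 1, 32))
    unlist(counts) / (3 * length(img[, , 1]))
  }
  ha <- h(mk(pre$non_failing)); hb <- h(mk(pre$failing))
  chisq <- sum((ha - hb)^2 / (ha + hb + 1e-12))
  expect_gt(chisq, 0)
})

test_that("synthetic slides have the requested tissue extent and background", {
  p <- tissue_params(0.1, rng_seed = 2)
  sl <- generate_slide(p, canvas_px = 600, tissue_extent_px = 450, rng_seed = 5)
  gray <- rgb_to_gray(sl$pixels)
  bg_frac <- mean(gray > 235)
  expect_lt(abs(bg_frac - (1 - 450^2 / 600^2)), 0.05)
  sl2 <- generate_slide(p, canvas_px = 600, tissue_extent_px = 450, rng_seed = 5)
  expect_identical(sl$pixels, sl2$pixels)
  expect_error(generate_slide(p, canvas_px = 400, tissue_extent_px = 400),
               class = "hf_invalid_argument")
})

test_that("cohorts have exact class counts and per-patient ROI counts", {
  spec <- cohort_spec(n_patients = 10, prop_failing = 0.5, rois_per_patient = 2,
                      roi_side_px = 128, rng_seed = 4)
  ch <- generate_cohort(spec)
  expect_equal(sum(ch$patients$label_v1 == "failing"), 5)
  expect_equal(sum(ch$patients$label_v1 == "non_failing"), 5)
  expect_equal(length(ch$rois), 10 * 2)
  per_pat <- table(vapply(ch$rois, `[[`, "", "patient_id"))
  expect_true(all(per_pat == 2))
  # total-ROI arithmetic scales as n_patients x rois_per_patient
  expect_equal(6 * 11, nrow(expand.grid(1:6, 1:11)))
})

test_that("occult patients come only from the non-failing pool and flip under schema v2", {
  spec <- cohort_spec(n_patients = 40, prop_failing = 0.5, occult_fraction = 0.1,
                      rois_per_patient = 1, roi_side_px = 128, rng_seed = 9)
  ch <- generate_cohort(spec)
  occ <- ch$patients[ch$patients$occult, ]
  expect_equal(nrow(occ), 2)  # round(20 * 0.1)
  expect_true(all(occ$label_v1 == "non_failing"))
  expect_true(all(occ$label_v2 == "abnormal_or_heart_failure"))
  # schema v1 -> v2 relabeling flips exactly the occult patients
  flipped <- with(ch$patients,
                  (label_v1 == "failing") != (label_v2 == "abnormal_or_heart_failure"))
  expect_equal(ch$patients$patient_id[flipped], occ$patient_id)
  expect_error(cohort_spec(10, prop_failing = 1.4), class = "hf_invalid_argument")
  expect_error(cohort_spec(10, occult_fraction = 2), class = "hf_invalid_argument")
})

test_that("a stroma-fraction discriminator improves with the preset effect size", {
  score <- function(effect, n = 100) {
    pre <- tissue_presets(effect)
    mid <- (pre$non_failing$fibrosis_fraction + pre$failing$fibrosis_fraction) / 2
    spec_f <- cohort_spec(n, prop_failing = 1, rois_per_patient = 1,
                          roi_side_px = 128, effect_size = effect, rng_seed = 21)
    spec_n <- cohort_spec(n, prop_failing = 0, rois_per_patient = 1,
                          roi_side_px = 128, effect_size = effect, rng_seed = 22)
    rois <- c(generate_cohort(spec_f)$rois, generate_cohort(spec_n)$rois)
    fr <- vapply(rois, function(r) measured_stroma_fraction(r$pixels), 0)
    truth <- rep(c(TRUE, FALSE), each = n)
    mean((fr > mid) == truth)
  }
  acc <- c(weak = score("weak"), moderate = score("moderate"),
           strong = score("strong"))
  expect_lt(acc["weak"], acc["moderate"])
  expect_lt(acc["moderate"], acc["strong"])
})

test_that("clustering fixtures have the planted geometry", {
  g1 <- generate_feature_clusters(1, 40, 0, 6, rng_seed = 2)
  d <- as.matrix(dist(g1$features))
  # mean pairwise distance of a unit-variance spherical cloud ~ sqrt(2p)
  expect_lt(abs(mean(d[upper.tri(d)]) - sqrt(2 * 6)) / sqrt(2 * 6), 0.15)

  g0 <- generate_feature_clusters(2, 40, 0, 6, rng_seed = 3)
  ct <- stats::cutree(stats::hclust(dist(g0$features), "average"), k = 2)
  tab <- table(ct, g0$assignments)
  agree <- max(sum(diag(tab)), sum(tab[1, 2] + tab[2, 1])) / sum(tab)
  expect_lt(agree, 0.7)  # separation 0: chance-level recovery

  g3 <- generate_feature_clusters(3, 30, 8, 5, rng_seed = 1)
  ct3 <- stats::cutree(stats::hclust(dist(g3$features), "average"), k = 3)
  expect_equal(length(unique(paste(ct3, g3$assignments))), 3)  # exact recovery

  expect_error(generate_feature_clusters(3, 10, 5, 2), class = "hf_invalid_argument")
})
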