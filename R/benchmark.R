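# The headline synthetic benchmark: reproduce the pipeline's operating point
# (patient-level sensitivity/specificity of the CNN arm) on a strong-effect
# synthetic cohort at desk scale.

#' Headline synthetic benchmark of the CNN arm
#'
#' Generates a strong-effect synthetic cohort, splits it in half at the
#' patient level (stratified), trains the reference network on rotation-
#' augmented patches from the training half, aggregates
#' pixel -> image -> patient on the held-out half, and reports the
#' patient-level operating point.
#'
#' Desk-scale defaults: 80 patients (40 train / 40 test), 11 ROIs per patient
#' at 192 px (2 um/px), 15 patches per ROI (x4 rotation augmentation), 15
#' epochs of SGD at batch 64.
#'
#' @param seed master seed; every random stage derives from it.
#' @param n_patients cohort size (default 80).
#' @param rois_per_patient ROIs per patient (default 11).
#' @param roi_side_px ROI side (default 192).
#' @param patches_per_roi patches sampled per ROI before augmentation
#'   (default 15).
#' @param epochs training epochs (default 15).
#' @param effect_size class separation (default `"strong"`).
#' @param occult_fraction occult-pathology fraction (default 0).
#' @return list: `sensitivity` and `specificity` in percent, `image_auc`,
#'   `patient_auc`, the patient table, per-image probabilities, the split and
#'   the trained model.
#' @export
run_headline_benchmark <- function(seed = 7L, n_patients = 80,
                                   rois_per_patient = 11, roi_side_px = 192,
                                   patches_per_roi = 15, epochs = 15,
                                   effect_size = "strong",
                                   occult_fraction = 0) {
  seeds <- derive_seeds(seed, 4L)
  spec <- cohort_spec(n_patients = n_patients, prop_failing = 0.5,
                      occult_fraction = occult_fraction,
                      rois_per_patient = rois_per_patient,
                      roi_side_px = roi_side_px, mpp = 2.0,
                      effect_size = effect_size, rng_seed = seeds[1])
  cohort <- generate_cohort(spec)
  split <- train_test_split(cohort, rng_seed = seeds[2])

  patches <- sample_cohort_patches(cohort, split$train,
                                   n_per_roi = patches_per_roi,
                                   rng_seed = seeds[3])
  patches <- augment_rotations(patches)
  model <- build_cnn(rng_seed = seeds[4])
  cfg <- training_config(epochs = epochs, batch_size = 64,
                         lr_step = max(2, round(epochs * 2 / 3)),
                         rng_seed = seeds[4])
  model <- train_cnn(model, patches, config = cfg)

  test_rois <- Filter(function(r) r$patient_id %in% split$test, cohort$rois)
  image_probs <- vapply(test_rois, function(r)
    image_probability(predict_probability_map(model, r)), 0)
  patient_ids <- vapply(test_rois, `[[`, "", "patient_id")
  labels <- cohort_labels(cohort)
  pats <- aggregate_patients(image_probs, patient_ids, labels)
  truth <- pats$label == "failing"
  m <- confusion_metrics(pats$diagnosis, truth)
  img_truth <- labels[patient_ids] == "failing"
  list(sensitivity = 100 * m$sensitivity,
       specificity = 100 * m$specificity,
       accuracy = 100 * m$accuracy,
       image_auc = roc_auc(image_probs, img_truth)$auc,
       patient_auc = roc_auc(pats$patient_prob, truth)$auc,
       patients = pats,
       image_probs = data.frame(patient_id = patient_ids,
                                roi_id = vapply(test_rois, `[[`, "", "roi_id"),
                                probability = unname(image_probs),
                                stringsAsFactors = FALSE),
       split = split, model = model, cohort_labels = labels,
       test_rois = test_rois)
}
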