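# End-to-end experiment orchestration: one config drives cohort creation (or
# loading), the patient-level split, per-fold training/validation of the
# requested model arms, retraining on the full training set, held-out
# evaluation and report generation.  Every stage writes its outputs (with
# checksums) into the run directory and is skipped on resume when its output
# already exists under an identical config.

#' Experiment configuration
#'
#' @param mode `"synthetic"` (a cohort is generated from `cohort`) or
#'   `"files"` (a cohort manifest directory is read from `cohort_dir`).
#' @param cohort an [cohort_spec()] (synthetic mode).
#' @param cohort_dir manifest directory (files mode).
#' @param schema label schema used for training/evaluation: `"v1"`
#'   (clinical) or `"v2"` (pathology-revised).
#' @param arms model arms to run: subset of `c("cnn", "charm_rf")`.
#' @param n_folds cross-validation folds (default 3).
#' @param split_seed,fold_seed seeds for the train/test split and folds.
#' @param patches_per_roi training patches sampled per ROI (default 100).
#' @param train_config an [training_config()] for the CNN arm.
#' @param mrmr_k,n_trees comparator-arm settings.
#' @param threshold image-call threshold (default 0.5).
#' @return object of class `hf_experiment_config`.
#' @export
experiment_config <- function(mode = c("synthetic", "files"), cohort = NULL,
                              cohort_dir = NULL, schema = c("v1", "v2"),
                              arms = c("cnn", "charm_rf"), n_folds = 3,
                              split_seed = 1L, fold_seed = 1L,
                              patches_per_roi = 100,
                              train_config = training_config(),
                              mrmr_k = 20, n_trees = 1000, threshold = 0.5) {
  mode <- match.arg(mode)
  schema <- match.arg(schema)
  arms <- match.arg(arms, several.ok = TRUE)
  if (mode == "synthetic" && !inherits(cohort, "hf_cohort_spec"))
    stop_invalid_argument("synthetic mode needs a cohort_spec() in `cohort`")
  if (mode == "files" && is.null(cohort_dir))
    stop_invalid_argument("files mode needs `cohort_dir`")
  structure(list(mode = mode, cohort = cohort, cohort_dir = cohort_dir,
                 schema = schema, arms = arms, n_folds = n_folds,
                 split_seed = as.integer(split_seed),
                 fold_seed = as.integer(fold_seed),
                 patches_per_roi = patches_per_roi,
                 train_config = train_config, mrmr_k = mrmr_k,
                 n_trees = n_trees, threshold = threshold),
            class = "hf_experiment_config")
}

config_hash <- function(config) {
  # content hash of the config (and so of everything a stage depends on)
  json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                           force = TRUE, null = "null")
  as.character(tools::md5sum(local({
    f <- tempfile(); writeLines(json, f); f
  })))
}

stage_log <- function(run_dir, stage, message) {
  line <- sprintf("%s\t%s\t%s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, message)
  cat(line, "\n", sep = "", file = file.path(run_dir, "stages.log"),
      append = TRUE)
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

# evaluate one arm's image probabilities on a set of patients
evaluate_arm <- function(image_probs, patient_ids, labels, positive,
                         threshold = 0.5) {
  image_calls <- image_prediction(image_probs, threshold)
  truth_image <- labels[patient_ids] == positive
  img_metrics <- confusion_metrics(image_calls, truth_image)
  img_roc <- roc_auc(image_probs, truth_image)
  pats <- aggregate_patients(image_probs, patient_ids, labels, threshold)
  truth_pat <- pats$label == positive
  pat_metrics <- confusion_metrics(pats$diagnosis, truth_pat)
  pat_roc <- roc_auc(pats$patient_prob, truth_pat)
  list(image = img_metrics, image_auc = img_roc$auc, image_roc = img_roc,
       patient = pat_metrics, patient_auc = pat_roc$auc, patient_roc = pat_roc,
       patients = pats)
}

metrics_row <- function(m, auc) {
  c(accuracy = m$accuracy, sensitivity = m$sensitivity,
    specificity = m$specificity, ppv = m$ppv, auc = auc)
}

# train the CNN arm on given patients, return image probabilities for
# evaluation patients
run_cnn_arm <- function(cohort, train_ids, eval_ids, config, seed_offset = 0L) {
  tc <- config$train_config
  patches <- sample_cohort_patches(
    cohort, train_ids, n_per_roi = config$patches_per_roi,
    rng_seed = tc$rng_seed + seed_offset, schema = config$schema)
  patches <- augment_rotations(patches)
  model <- build_cnn(rng_seed = tc$rng_seed + seed_offset)
  tc2 <- tc; tc2$rng_seed <- tc$rng_seed + seed_offset + 1L
  model <- train_cnn(model, patches, config = tc2)
  eval_rois <- Filter(function(r) r$patient_id %in% eval_ids, cohort$rois)
  probs <- vapply(eval_rois,
                  function(r) image_probability(predict_probability_map(model, r)),
                  0)
  list(model = model,
       probs = data.frame(
         patient_id = vapply(eval_rois, `[[`, "", "patient_id"),
         roi_id = vapply(eval_rois, `[[`, "", "roi_id"),
         model = "cnn", probability = unname(probs),
         stringsAsFactors = FALSE))
}

# train the engineered-feature arm; `features` is the precomputed full
# feature matrix for the whole cohort
run_charm_arm <- function(cohort, features, train_ids, eval_ids, config,
                          seed_offset = 0L) {
  pats <- attr(features, "patient_id")
  labels <- cohort_labels(cohort, config$schema)
  tr <- pats %in% train_ids
  ev <- pats %in% eval_ids
  model <- fit_charm(features[tr, , drop = FALSE], labels[pats[tr]],
                     k = config$mrmr_k, n_trees = config$n_trees,
                     rng_seed = config$train_config$rng_seed + seed_offset)
  probs <- rf_predict(model, features[ev, , drop = FALSE])
  list(model = model,
       probs = data.frame(patient_id = pats[ev],
                          roi_id = rownames(features)[ev],
                          model = "charm_rf", probability = probs,
                          stringsAsFactors = FALSE))
}

#' Run an end-to-end experiment
#'
#' Stages: cohort -> train/test split -> per-fold train/validate ->
#' retrain on the full training set -> held-out evaluation -> reports.
#' Outputs land in `run_dir`: `manifest.json` (config, seeds, hash),
#' `predictions_val.csv` / `predictions_test.csv`, `metrics.json`
#' (mean +- sd over the fold models at the validation level, plus the
#' full-training-set held-out metrics), `roc_test_<arm>.csv`, `stages.log`
#' and `checksums.txt`.  Re-running with the same config resumes (completed
#' runs are not recomputed); a differing config against an existing run
#' directory raises a config-drift error.
#'
#' @param config an [experiment_config()].
#' @param run_dir output directory.
#' @return invisibly, a list with the metrics and prediction tables.
#' @export
run_experiment <- function(config, run_dir) {
  if (!inherits(config, "hf_experiment_config"))
    stop_invalid_argument("`config` must come from experiment_config()")
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  man_path <- file.path(run_dir, "manifest.json")
  if (file.exists(man_path)) {
    prev <- jsonlite::read_json(man_path)
    if (!identical(prev$config_hash, hash))
      stop_config_drift("run directory holds a different configuration")
    if (isTRUE(prev$complete)) {
      stage_log(run_dir, "resume", "run already complete; nothing to do")
      return(invisible(readRDS(file.path(run_dir, "results.rds"))))
    }
  }
  write_json_file(list(config_hash = hash, schema = config$schema,
                       arms = config$arms, split_seed = config$split_seed,
                       fold_seed = config$fold_seed,
                       train_seed = config$train_config$rng_seed,
                       complete = FALSE), man_path)

  # stage: cohort
  cohort <- if (config$mode == "synthetic") generate_cohort(config$cohort)
            else read_cohort(config$cohort_dir)
  labels <- cohort_labels(cohort, config$schema)
  positive <- positive_label(config$schema)
  stage_log(run_dir, "cohort", sprintf("%d patients, %d ROIs",
                                       nrow(cohort$patients), length(cohort$rois)))

  # stage: split and folds (leakage guard asserted on every run)
  split <- train_test_split(cohort, rng_seed = config$split_seed,
                            schema = config$schema)
  stopifnot(length(intersect(split$train, split$test)) == 0)
  folds <- crossval_split(cohort$patients[cohort$patients$patient_id %in%
                                            split$train, , drop = FALSE],
                          n_folds = config$n_folds,
                          rng_seed = config$fold_seed, schema = config$schema)
  stage_log(run_dir, "split", sprintf("%d train / %d test, %d folds",
                                      length(split$train), length(split$test),
                                      config$n_folds))

  features <- NULL
  if ("charm_rf" %in% config$arms) {
    features <- extract_feature_matrix(cohort)
    stage_log(run_dir, "features", sprintf("%d x %d feature matrix",
                                           nrow(features), ncol(features)))
  } else {
    stage_log(run_dir, "features", "skipped (cnn arm only)")
  }

  # stage: fold loop -- train on n-1 folds, validate on the held-out fold
  val_rows <- list()
  val_metrics <- list()
  for (f in sort(unique(folds))) {
    tr_ids <- names(folds)[folds != f]
    va_ids <- names(folds)[folds == f]
    for (arm in config$arms) {
      res <- if (arm == "cnn")
        run_cnn_arm(cohort, tr_ids, va_ids, config, seed_offset = f)
      else
        run_charm_arm(cohort, features, tr_ids, va_ids, config, seed_offset = f)
      ev <- evaluate_arm(res$probs$probability, res$probs$patient_id, labels,
                         positive, config$threshold)
      res$probs$fold <- f
      val_rows[[paste(arm, f)]] <- res$probs
      val_metrics[[arm]] <- rbind(
        val_metrics[[arm]],
        rbind(image = metrics_row(ev$image, ev$image_auc),
              patient = metrics_row(ev$patient, ev$patient_auc)))
      stage_log(run_dir, "fold",
                sprintf("fold %d arm %s: patient acc %.3f", f, arm,
                        ev$patient$accuracy))
    }
  }
  pred_val <- do.call(rbind, val_rows)
  utils::write.csv(pred_val, file.path(run_dir, "predictions_val.csv"),
                   row.names = FALSE)

  # stage: retrain on the full training set, evaluate held out
  test_rows <- list()
  test_eval <- list()
  for (arm in config$arms) {
    res <- if (arm == "cnn")
      run_cnn_arm(cohort, split$train, split$test, config, seed_offset = 0L)
    else
      run_charm_arm(cohort, features, split$train, split$test, config,
                    seed_offset = 0L)
    ev <- evaluate_arm(res$probs$probability, res$probs$patient_id, labels,
                       positive, config$threshold)
    test_rows[[arm]] <- res$probs
    test_eval[[arm]] <- ev
    roc_df <- data.frame(fpr = ev$image_roc$fpr, tpr = ev$image_roc$tpr)
    utils::write.csv(roc_df, file.path(run_dir, sprintf("roc_test_%s.csv", arm)),
                     row.names = FALSE)
    stage_log(run_dir, "test", sprintf(
      "arm %s: patient acc %.3f sens %.3f spec %.3f auc %.3f", arm,
      ev$patient$accuracy, ev$patient$sensitivity, ev$patient$specificity,
      ev$patient_auc))
  }
  pred_test <- do.call(rbind, test_rows)
  utils::write.csv(pred_test, file.path(run_dir, "predictions_test.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$patients, file.path(run_dir, "patients.csv"),
                   row.names = FALSE)

  # reports: validation mean +- sd over fold models, held-out point metrics
  metrics <- list()
  for (arm in config$arms) {
    vm <- val_metrics[[arm]]
    img <- vm[rownames(vm) == "image", , drop = FALSE]
    pat <- vm[rownames(vm) == "patient", , drop = FALSE]
    ev <- test_eval[[arm]]
    metrics[[arm]] <- list(
      validation = list(
        image = list(mean = as.list(colMeans(img)),
                     sd = as.list(apply(img, 2, stats::sd))),
        patient = list(mean = as.list(colMeans(pat)),
                       sd = as.list(apply(pat, 2, stats::sd)))),
      test = list(
        image = as.list(metrics_row(ev$image, ev$image_auc)),
        patient = as.list(metrics_row(ev$patient, ev$patient_auc))))
  }
  write_json_file(metrics, file.path(run_dir, "metrics.json"))

  # figures: test ROC curves
  grDevices::png(file.path(run_dir, "roc_test.png"), width = 600, height = 600)
  graphics::plot(0:1, 0:1, type = "n", xlab = "false positive rate",
                 ylab = "true positive rate", main = "held-out image-level ROC")
  cols <- c(cnn = "firebrick", charm_rf = "steelblue")
  for (arm in config$arms)
    graphics::lines(test_eval[[arm]]$image_roc$fpr,
                    test_eval[[arm]]$image_roc$tpr, col = cols[[arm]], lwd = 2)
  graphics::legend("bottomright", legend = config$arms,
                   col = cols[config$arms], lwd = 2)
  grDevices::dev.off()

  # checksums over the emitted artifacts
  arts <- list.files(run_dir, pattern = "\\.(csv|json|png)$", full.names = TRUE)
  sums <- tools::md5sum(arts)
  writeLines(sprintf("%s  %s", sums, basename(names(sums))),
             file.path(run_dir, "checksums.txt"))

  results <- list(metrics = metrics, predictions_val = pred_val,
                  predictions_test = pred_test, patients = cohort$patients,
                  split = split, folds = folds)
  saveRDS(results, file.path(run_dir, "results.rds"))
  write_json_file(list(config_hash = hash, schema = config$schema,
                       arms = config$arms, split_seed = config$split_seed,
                       fold_seed = config$fold_seed,
                       train_seed = config$train_config$rng_seed,
                       complete = TRUE), man_path)
  stage_log(run_dir, "done", "run complete")
  invisible(results)
}

#' Re-score a completed run under another label schema
#'
#' Recomputes all held-out metrics from the stored predictions without
#' retraining (retraining under the new schema is available by re-running
#' [run_experiment()] with `schema` changed).
#'
#' @param run_dir a completed run directory.
#' @param schema `"v1"` or `"v2"`.
#' @return list of per-arm metric lists (image and patient level).
#' @export
relabel_and_rescore <- function(run_dir, schema = c("v1", "v2")) {
  schema <- match.arg(schema)
  pred_path <- file.path(run_dir, "predictions_test.csv")
  pat_path <- file.path(run_dir, "patients.csv")
  if (!file.exists(pred_path) || !file.exists(pat_path))
    stop_invalid_state("run directory lacks stored predictions")
  preds <- utils::read.csv(pred_path, stringsAsFactors = FALSE)
  patients <- utils::read.csv(pat_path, stringsAsFactors = FALSE)
  labels <- cohort_labels(patients, schema)
  positive <- positive_label(schema)
  out <- list()
  for (arm in unique(preds$model)) {
    sub <- preds[preds$model == arm, , drop = FALSE]
    ev <- evaluate_arm(sub$probability, sub$patient_id, labels, positive)
    out[[arm]] <- list(image = as.list(metrics_row(ev$image, ev$image_auc)),
                       patient = as.list(metrics_row(ev$patient, ev$patient_auc)))
  }
  out
}
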