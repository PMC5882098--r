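# Probability aggregation (image -> patient), evaluation metrics and the
# statistical comparisons, plus patient-level data splits.
#
# Aggregation scheme: pixel probabilities are averaged to an image
# probability; images with probability strictly greater than 0.5 are called
# failing; the fraction of failing image calls is the patient probability;
# the patient diagnosis is the majority vote (strictly greater than 0.5 --
# with 11 images per patient no tie can occur).

#' Image-level class call
#'
#' Failing if and only if the probability is strictly greater than the
#' threshold ("probabilities greater than 50%").
#'
#' @param prob probability (vectorized), each in `[0, 1]`.
#' @param threshold decision threshold (default 0.5).
#' @return logical vector: `TRUE` = failing.
#' @export
image_prediction <- function(prob, threshold = 0.5) {
  if (any(!is.finite(prob)) || any(prob < 0) || any(prob > 1))
    stop_invalid_argument("probabilities must lie in [0, 1]")
  prob > threshold
}

#' Patient-level probability
#'
#' The fraction of a patient's images called failing.
#'
#' @param image_calls logical (or 0/1) vector of image calls.
#' @return proportion in `[0, 1]`.
#' @export
patient_probability <- function(image_calls) {
  if (length(image_calls) == 0) stop_degenerate_input("no image calls")
  mean(as.logical(image_calls))
}

#' Patient-level diagnosis
#'
#' Majority vote over the patient's images: failing iff the patient
#' probability strictly exceeds 0.5 (an exact 0.5 with an even image count is
#' called non-failing).
#'
#' @param patient_prob proportion in `[0, 1]` (vectorized).
#' @return logical: `TRUE` = failing.
#' @export
patient_diagnosis <- function(patient_prob) {
  if (any(patient_prob < 0 | patient_prob > 1))
    stop_invalid_argument("patient probability must lie in [0, 1]")
  patient_prob > 0.5
}

#' Confusion-matrix metrics
#'
#' @param calls predicted classes (logical failing, or labels).
#' @param truths true classes (same coding).
#' @param positive value of `calls`/`truths` treated as the positive
#'   (failing) class when they are not logical.
#' @return object of class `hf_metrics`: TP/FP/TN/FN counts plus accuracy,
#'   sensitivity, specificity and positive predictive value.  A ratio with an
#'   empty denominator is `NA` (with a warning), never silently zero.
#' @export
confusion_metrics <- function(calls, truths, positive = TRUE) {
  if (length(calls) != length(truths))
    stop_invalid_argument("`calls` and `truths` differ in length")
  pc <- calls == positive
  pt <- truths == positive
  tp <- sum(pc & pt); fp <- sum(pc & !pt)
  tn <- sum(!pc & !pt); fn <- sum(!pc & pt)
  safe_ratio <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s is undefined (empty denominator)", what),
              call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    accuracy = (tp + tn) / length(calls),
    sensitivity = safe_ratio(tp, tp + fn, "sensitivity"),
    specificity = safe_ratio(tn, tn + fp, "specificity"),
    ppv = safe_ratio(tp, tp + fp, "positive predictive value")),
    class = "hf_metrics")
}

#' @export
print.hf_metrics <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("accuracy %.3f  sensitivity %.3f  specificity %.3f  ppv %.3f\n",
              x$accuracy, x$sensitivity, x$specificity, x$ppv))
  invisible(x)
}

#' ROC curve and AUC
#'
#' The curve is swept over all distinct score thresholds (tied scores cross
#' their threshold simultaneously); the area is the trapezoidal integral,
#' which equals the tie-corrected rank-sum statistic U/(n1*n2).
#'
#' @param scores numeric scores (higher = more failing-like).
#' @param truths true classes.
#' @param positive positive-class value in `truths`.
#' @return object of class `hf_roc`: `fpr`, `tpr`, `thresholds`, `auc`.
#' @export
roc_auc <- function(scores, truths, positive = TRUE) {
  y <- truths == positive
  if (length(scores) != length(y))
    stop_invalid_argument("`scores` and `truths` differ in length")
  if (all(y) || !any(y))
    stop_invalid_data("both classes must be present for a ROC curve")
  n1 <- sum(y); n0 <- sum(!y)
  thr <- sort(unique(scores), decreasing = TRUE)
  # counts of positives/negatives at each distinct score, descending
  pos_at <- vapply(thr, function(t) sum(scores == t & y), 0)
  neg_at <- vapply(thr, function(t) sum(scores == t & !y), 0)
  tpr <- c(0, cumsum(pos_at) / n1)
  fpr <- c(0, cumsum(neg_at) / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(fpr = fpr, tpr = tpr, thresholds = c(Inf, thr), auc = auc),
            class = "hf_roc")
}

#' @export
print.hf_roc <- function(x, ...) {
  cat(sprintf("<hf_roc> %d points, AUC = %.4f\n", length(x$fpr), x$auc))
  invisible(x)
}

#' @export
plot.hf_roc <- function(x, ...) {
  graphics::plot(x$fpr, x$tpr, type = "l", xlab = "false positive rate",
                 ylab = "true positive rate", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement kappa = (p_o - p_e) / (1 - p_e), with the
#' expected agreement p_e from the product of the raters' marginals.
#'
#' @param ratings_a,ratings_b equal-length categorical vectors.
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(ratings_a, ratings_b) {
  if (length(ratings_a) != length(ratings_b))
    stop_invalid_argument("rating vectors differ in length")
  lev <- union(unique(ratings_a), unique(ratings_b))
  a <- factor(ratings_a, levels = lev)
  b <- factor(ratings_b, levels = lev)
  tab <- table(a, b) / length(a)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (pe >= 1)
    stop_degenerate_input("both raters are constant and equal: kappa undefined")
  (po - pe) / (1 - pe)
}

#' Unpaired two-sample t-test (pooled variance)
#'
#' @param sample_a,sample_b numeric samples of size >= 2.
#' @return list `t`, `df`, `p` (two-sided).
#' @export
unpaired_ttest <- function(sample_a, sample_b) {
  na <- length(sample_a); nb <- length(sample_b)
  if (na < 2 || nb < 2) stop_invalid_argument("each sample needs >= 2 values")
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(sample_a) + (nb - 1) * stats::var(sample_b)) / df
  delta <- mean(sample_a) - mean(sample_b)
  if (sp2 == 0) {
    if (delta == 0) return(list(t = 0, df = df, p = 1))
    warning("zero pooled variance with unequal means: p reported as 0",
            call. = FALSE)
    return(list(t = sign(delta) * Inf, df = df, p = 0))
  }
  tval <- delta / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' One-sample t-test against a reference value
#'
#' @param sample numeric sample of size >= 2.
#' @param reference_value the constant to compare against.
#' @return list `t`, `df`, `p` (two-sided).
#' @export
one_sample_ttest <- function(sample, reference_value) {
  n <- length(sample)
  if (n < 2) stop_invalid_argument("sample needs >= 2 values")
  df <- n - 1
  s <- stats::sd(sample)
  delta <- mean(sample) - reference_value
  if (s == 0) {
    if (delta == 0) return(list(t = 0, df = df, p = 1))
    warning("zero variance with mean != reference: p reported as 0",
            call. = FALSE)
    return(list(t = sign(delta) * Inf, df = df, p = 0))
  }
  tval <- delta / (s / sqrt(n))
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' D = sup |F_a - F_b| with the asymptotic two-sided p value.
#'
#' @param sample_a,sample_b non-empty numeric samples.
#' @return list `D`, `p`.
#' @export
ks_compare <- function(sample_a, sample_b) {
  if (length(sample_a) == 0 || length(sample_b) == 0)
    stop_invalid_argument("samples must be non-empty")
  res <- suppressWarnings(stats::ks.test(sample_a, sample_b, exact = FALSE))
  list(D = unname(res$statistic), p = unname(res$p.value))
}

#' Kolmogorov-Smirnov comparison of two ROC curves
#'
#' Both curves are interpolated (step-wise) onto a common 1001-point
#' false-positive-rate grid and their TPR samples are compared with the
#' two-sample KS test.  This mirrors the published comparison of image-level
#' ROC curves; it is a curve-shape comparison, not a test on the underlying
#' scores.
#'
#' @param roc_a,roc_b `hf_roc` objects.
#' @param grid_points number of FPR grid points (default 1001).
#' @return list `D`, `p`.
#' @export
ks_compare_roc <- function(roc_a, roc_b, grid_points = 1001) {
  grid <- seq(0, 1, length.out = grid_points)
  interp <- function(r) stats::approx(r$fpr, r$tpr, xout = grid,
                                      method = "constant", ties = max,
                                      rule = 2)$y
  ks_compare(interp(roc_a), interp(roc_b))
}

#' Label-stratified k-fold split at the patient level
#'
#' Every patient lands in exactly one fold; within each label the fold sizes
#' differ by at most one.  All of a patient's ROIs and patches follow the
#' patient.
#'
#' @param patient_table data frame with `patient_id` and a label column
#'   (`label_v1` used), or an `hf_cohort`.
#' @param n_folds number of folds (default 3).
#' @param rng_seed integer seed.
#' @param schema label schema used for stratification.
#' @return named integer vector: patient id -> fold in `1..n_folds`.
#' @export
crossval_split <- function(patient_table, n_folds = 3, rng_seed = 1L,
                           schema = c("v1", "v2")) {
  schema <- match.arg(schema)
  labs <- cohort_labels(patient_table, schema)
  n_folds <- check_count(n_folds, "n_folds", min = 2L)
  if (n_folds > length(labs))
    stop_invalid_argument("more folds than patients")
  fold <- stats::setNames(integer(length(labs)), names(labs))
  withr::with_seed(as.integer(rng_seed), {
    for (lv in unique(labs)) {
      ids <- sample(names(labs)[labs == lv])
      fold[ids] <- rep_len(seq_len(n_folds), length(ids))
    }
  })
  fold
}

#' Label-stratified train/test split at the patient level
#'
#' floor(n/2) patients are designated for training and the remainder held
#' out, preserving the class ratio within one patient.
#'
#' @param patient_table data frame with `patient_id` and labels, or an
#'   `hf_cohort`.
#' @param rng_seed integer seed.
#' @param schema label schema used for stratification.
#' @return list with `train` and `test` character vectors of patient ids.
#' @export
train_test_split <- function(patient_table, rng_seed = 1L,
                             schema = c("v1", "v2")) {
  schema <- match.arg(schema)
  labs <- cohort_labels(patient_table, schema)
  n <- length(labs)
  if (n < 2) stop_invalid_argument("need at least two patients")
  target_train <- n %/% 2
  train <- character(0)
  withr::with_seed(as.integer(rng_seed), {
    ids <- sample(names(labs))
    shuffled <- split(ids, labs[ids])
    # stratified floor split, topping up from the largest remainders
    takes <- vapply(shuffled, function(ids) length(ids) %/% 2L, 1L)
    short <- target_train - sum(takes)
    if (short > 0) {
      rema <- vapply(shuffled, function(ids) length(ids) %% 2L, 1L)
      ord <- order(rema, decreasing = TRUE)
      for (i in seq_len(short)) {
        g <- ord[(i - 1) %% length(shuffled) + 1]
        takes[g] <- takes[g] + 1L
      }
    }
    for (g in seq_along(shuffled))
      train <- c(train, utils::head(shuffled[[g]], takes[g]))
  })
  list(train = train, test = setdiff(names(labs), train))
}

#' Aggregate image probabilities to patient records
#'
#' @param image_probs numeric vector of image-level failing probabilities.
#' @param patient_ids patient id of each image.
#' @param labels named vector of patient labels (as from [cohort_labels()]).
#' @param threshold image-call threshold (default 0.5, strict).
#' @return data frame: one row per patient with `patient_id`, `label`,
#'   `n_images`, `patient_prob` (fraction of failing image calls) and
#'   `diagnosis` (majority vote).
#' @export
aggregate_patients <- function(image_probs, patient_ids, labels,
                               threshold = 0.5) {
  calls <- image_prediction(image_probs, threshold)
  by_pat <- split(calls, patient_ids)
  prob <- vapply(by_pat, patient_probability, 0)
  data.frame(patient_id = names(by_pat),
             label = unname(labels[names(by_pat)]),
             n_images = vapply(by_pat, length, 1L),
             patient_prob = unname(prob),
             diagnosis = unname(patient_diagnosis(prob)),
             stringsAsFactors = FALSE, row.names = NULL)
}
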