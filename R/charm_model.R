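# The comparator arm: z-scoring, mRMR feature selection, and a 1000-tree
# random forest producing image-level failing probabilities.

# tercile-style discretization at mean +- sd/2 (3 levels)
discretize_terciles <- function(x) {
  m <- mean(x); s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(1L, length(x)))
  cut_lo <- m - s / 2; cut_hi <- m + s / 2
  1L + (x > cut_lo) + (x > cut_hi)
}

# mutual information (nats) between two discrete vectors
mutual_information <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  idx <- p > 0
  sum(p[idx] * log(p[idx] / outer(px, py)[idx]))
}

#' Minimum-redundancy maximum-relevance feature selection
#'
#' Greedy forward selection with the difference (MID) criterion: the first
#' feature maximizes the relevance I(f; y); each later pick maximizes
#' I(f; y) - mean over selected s of I(f; s).  Mutual information is computed
#' on per-feature tercile-discretized values (cut points at mean +- sd/2).
#' Ties break toward the lowest feature index, making the selection
#' deterministic.
#'
#' @param features numeric feature matrix (rows = items).
#' @param labels class labels (two classes required).
#' @param k number of features to select (default 20).
#' @return object of class `hf_selected_features`: `indices` (ordered),
#'   `scores` (criterion value at each pick), `k`, `feature_names`.
#' @export
mrmr_select <- function(features, labels, k = 20) {
  features <- as.matrix(features)
  k <- check_count(k, "k")
  if (k > ncol(features))
    stop_invalid_argument("`k` exceeds the number of features")
  if (length(unique(labels)) < 2L)
    stop_invalid_data("labels are constant: relevance is undefined")
  if (length(labels) != nrow(features))
    stop_invalid_argument("labels/features length mismatch")
  disc <- apply(features, 2, discretize_terciles)
  y <- as.integer(factor(labels))
  p <- ncol(features)
  relevance <- vapply(seq_len(p), function(j) mutual_information(disc[, j], y), 0)
  selected <- integer(0)
  scores <- numeric(0)
  # pairwise feature MI computed lazily as columns enter the selected set
  red <- matrix(NA_real_, p, 0)
  for (step in seq_len(k)) {
    if (length(selected) == 0L) {
      crit <- relevance
    } else {
      crit <- relevance - rowMeans(red, na.rm = FALSE)
    }
    crit[selected] <- -Inf
    pick <- which.max(crit)  # first maximum = lowest index on ties
    selected <- c(selected, pick)
    scores <- c(scores, crit[pick])
    if (step < k) {
      mi_new <- vapply(seq_len(p), function(j)
        if (j %in% selected) 0 else mutual_information(disc[, j], disc[, pick]), 0)
      red <- cbind(red, mi_new)
    }
  }
  structure(list(indices = selected, scores = scores, k = k,
                 feature_names = colnames(features)[selected]),
            class = "hf_selected_features")
}

#' @export
print.hf_selected_features <- function(x, ...) {
  cat(sprintf("<hf_selected_features> k = %d\n", x$k))
  nm <- if (is.null(x$feature_names)) as.character(x$indices) else x$feature_names
  cat(" ", paste(utils::head(nm, 10), collapse = ", "),
      if (x$k > 10) "..." else "", "\n")
  invisible(x)
}

#' Train the random-forest stage
#'
#' Breiman-style forest: bootstrap-bagged trees, sqrt(p) candidate features
#' per split, grown to purity; 1000 trees by default.
#'
#' @param features numeric matrix of (selected) features, rows = items.
#' @param labels two-class labels.
#' @param n_trees ensemble size (default 1000).
#' @param rng_seed integer seed.
#' @return a fitted `randomForest` object.
#' @export
train_rf <- function(features, labels, n_trees = 1000, rng_seed = 1L) {
  features <- as.matrix(features)
  y <- factor(labels)
  if (nlevels(y) < 2L || min(table(y)) < 2L)
    stop_invalid_data("both classes need at least two samples")
  withr::with_seed(as.integer(rng_seed),
    randomForest::randomForest(x = features, y = y, ntree = n_trees,
                               mtry = max(1, floor(sqrt(ncol(features)))),
                               nodesize = 1))
}

#' Fit the full engineered-feature arm
#'
#' Pipeline: z-score the feature matrix with training-set statistics, select
#' `k` features by mRMR (or an alternative selector), and train the forest on
#' the selected standardized features.
#'
#' @param features training feature matrix (rows = ROIs).
#' @param labels training labels (patient label of each ROI).
#' @param k number of selected features (default 20).
#' @param n_trees forest size (default 1000).
#' @param selector `"mrmr"` (default) or the alternative univariate rankers
#'   `"wilcoxon"` / `"fisher"` (kept for comparison; not used by default).
#' @param rng_seed integer seed.
#' @return object of class `hf_charm`: standardization statistics, the
#'   selection, and the fitted forest.
#' @export
fit_charm <- function(features, labels, k = 20, n_trees = 1000,
                      selector = c("mrmr", "wilcoxon", "fisher"),
                      rng_seed = 1L) {
  selector <- match.arg(selector)
  features <- as.matrix(features)
  center <- colMeans(features)
  scale <- apply(features, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  Z <- sweep(sweep(features, 2, center), 2, scale, "/")
  y <- label_to_binary(labels)
  sel <- switch(selector,
    mrmr = mrmr_select(Z, labels, k = k),
    wilcoxon = {
      pv <- apply(Z, 2, function(col)
        stats::wilcox.test(col[y], col[!y], exact = FALSE)$p.value)
      structure(list(indices = order(pv)[seq_len(k)], scores = sort(pv)[seq_len(k)],
                     k = k, feature_names = colnames(Z)[order(pv)[seq_len(k)]]),
                class = "hf_selected_features")
    },
    fisher = {
      fs <- apply(Z, 2, function(col) {
        m1 <- mean(col[y]); m0 <- mean(col[!y])
        v1 <- stats::var(col[y]); v0 <- stats::var(col[!y])
        if (v1 + v0 == 0) 0 else (m1 - m0)^2 / (v1 + v0)
      })
      ord <- order(fs, decreasing = TRUE)
      structure(list(indices = ord[seq_len(k)], scores = fs[ord[seq_len(k)]],
                     k = k, feature_names = colnames(Z)[ord[seq_len(k)]]),
                class = "hf_selected_features")
    })
  forest <- train_rf(Z[, sel$indices, drop = FALSE], labels,
                     n_trees = n_trees, rng_seed = rng_seed)
  structure(list(center = center, scale = scale, selection = sel,
                 forest = forest, selector = selector,
                 positive = sort(unique(labels[y]))[1]),
            class = "hf_charm")
}

#' Image-level failing probability from the forest
#'
#' The probability is the fraction of trees voting for the failing class.
#'
#' @param model an `hf_charm` (or bare `randomForest`).
#' @param features feature matrix (raw scale for `hf_charm`: training
#'   standardization and selection are re-applied; already-selected columns
#'   for a bare forest).
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
rf_predict <- function(model, features) {
  features <- as.matrix(features)
  if (inherits(model, "hf_charm")) {
    if (ncol(features) != length(model$center))
      stop_invalid_argument("feature dimension mismatch with training")
    Z <- sweep(sweep(features, 2, model$center), 2, model$scale, "/")
    Z <- Z[, model$selection$indices, drop = FALSE]
    forest <- model$forest
    pos <- model$positive
  } else {
    forest <- model
    Z <- features
    if (ncol(Z) != length(forest$forest$ncat))
      stop_invalid_argument("feature dimension mismatch with training")
    pos <- intersect(c("failing", "abnormal_or_heart_failure"),
                     colnames(forest$votes))[1]
  }
  pr <- stats::predict(forest, Z, type = "vote", norm.votes = TRUE)
  unname(pr[, pos])
}

#' @export
print.hf_charm <- function(x, ...) {
  cat(sprintf("<hf_charm> %d features in, %d selected (%s), %d trees\n",
              length(x$center), x$selection$k, x$selector, x$forest$ntree))
  invisible(x)
}

#' @export
predict.hf_charm <- function(object, newdata, ...) rf_predict(object, newdata)
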