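# Consensus clustering: resampling-based clustering stability analysis.
#
# Repeatedly subsample the items, cluster each subsample with average-linkage
# hierarchical clustering on Euclidean distance of z-scored features, and
# record for every item pair the proportion of co-inclusions in which the
# pair co-clustered.  The per-k consensus CDFs and their incremental areas
# guide the choice of the number of clusters; clusters at the selected k are
# annotated by majority label to flag patients whose images cluster away from
# their labeled class.

#' Consensus clustering over a range of cluster numbers
#'
#' @param features numeric matrix (rows = items, e.g. image-level feature
#'   vectors).
#' @param k_range integer vector of cluster numbers to assess (all >= 2 and
#'   < number of items).
#' @param n_resamples number of subsamples (default 500).
#' @param item_fraction fraction of items per subsample (default 0.8).
#' @param rng_seed integer seed.
#' @param item_patients optional patient id per item (kept for downstream
#'   flagging).
#' @return object of class `hf_consensus`: per-k consensus matrices (entries
#'   in `[0,1]`, unit diagonal, `NA` for never-co-included pairs), per-k item
#'   assignments from consensus-matrix clustering, and bookkeeping.
#' @export
consensus_cluster <- function(features, k_range = 2:6, n_resamples = 500,
                              item_fraction = 0.8, rng_seed = 1L,
                              item_patients = NULL) {
  features <- as.matrix(features)
  n <- nrow(features)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2) stop_invalid_argument("k_range values must be >= 2")
  if (max(k_range) >= n) stop_invalid_argument("k must be below the item count")
  if (item_fraction <= 0 || item_fraction > 1)
    stop_invalid_argument("`item_fraction` must lie in (0, 1]")
  n_resamples <- check_count(n_resamples, "n_resamples")
  # z-score features (constant columns left at zero)
  sds <- apply(features, 2, stats::sd)
  sds[!is.finite(sds) | sds == 0] <- 1
  Z <- sweep(sweep(features, 2, colMeans(features)), 2, sds, "/")
  m <- ceiling(item_fraction * n)
  co <- lapply(k_range, function(k) matrix(0, n, n))
  names(co) <- as.character(k_range)
  inc <- matrix(0, n, n)
  withr::with_seed(as.integer(rng_seed), {
    for (r in seq_len(n_resamples)) {
      sub <- sort(sample.int(n, m))
      inc[sub, sub] <- inc[sub, sub] + 1
      hc <- stats::hclust(stats::dist(Z[sub, , drop = FALSE]), method = "average")
      for (ki in seq_along(k_range)) {
        ct <- stats::cutree(hc, k = k_range[ki])
        for (grp in split(sub, ct)) {
          co[[ki]][grp, grp] <- co[[ki]][grp, grp] + 1
        }
      }
    }
  })
  matrices <- lapply(co, function(M) {
    cons <- M / inc
    cons[inc == 0] <- NA_real_
    diag(cons) <- 1
    cons
  })
  # item assignments at each k: average-linkage on the consensus
  # dissimilarity (1 - consensus), the standard read-out
  assignments <- lapply(seq_along(k_range), function(ki) {
    D <- 1 - matrices[[ki]]
    D[is.na(D)] <- 1
    stats::cutree(stats::hclust(stats::as.dist(D), method = "average"),
                  k = k_range[ki])
  })
  names(assignments) <- as.character(k_range)
  structure(list(k_range = k_range, matrices = matrices,
                 assignments = assignments,
                 item_ids = rownames(features),
                 item_patients = item_patients,
                 n_resamples = n_resamples, item_fraction = item_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "hf_consensus")
}

#' @export
print.hf_consensus <- function(x, ...) {
  cat(sprintf("<hf_consensus> %d items, k in {%s}, %d resamples (fraction %.2f)\n",
              nrow(x$matrices[[1]]), paste(x$k_range, collapse = ", "),
              x$n_resamples, x$item_fraction))
  invisible(x)
}

#' Consensus CDFs, areas and delta-areas
#'
#' The empirical CDF of the upper-triangle consensus entries is computed per
#' k (never-co-included pairs excluded); its area on `[0, 1]` is integrated
#' by the trapezoid rule; the delta-area of k is the relative area gain over
#' the previous k (for the smallest k, the area itself).
#'
#' @param result an `hf_consensus`.
#' @param grid_points CDF evaluation grid size (default 1001).
#' @return list with `cdf` (list of functions), `area` (named numeric),
#'   `delta_area` (named numeric).
#' @export
consensus_cdf <- function(result, grid_points = 1001) {
  if (!inherits(result, "hf_consensus"))
    stop_invalid_argument("`result` must come from consensus_cluster()")
  grid <- seq(0, 1, length.out = grid_points)
  area <- numeric(length(result$k_range))
  cdfs <- vector("list", length(result$k_range))
  for (ki in seq_along(result$k_range)) {
    M <- result$matrices[[ki]]
    vals <- M[upper.tri(M)]
    vals <- vals[!is.na(vals)]
    F <- stats::ecdf(vals)
    cdfs[[ki]] <- F
    y <- F(grid)
    area[ki] <- sum(diff(grid) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  }
  names(area) <- as.character(result$k_range)
  delta <- c(area[1], diff(area) / utils::head(area, -1))
  names(delta) <- as.character(result$k_range)
  list(cdf = cdfs, area = area, delta_area = delta)
}

#' Select the number of clusters
#'
#' The point where adding a cluster stops increasing the consensus CDF area
#' appreciably.  A k is a significant structure boundary when its delta-area
#' is at least `delta_threshold` and dominates the mean of all later
#' delta-areas by `gain_ratio` (for real structure the area gain collapses
#' once the true cluster number is reached, while spurious splits keep
#' producing small steady gains).  The largest significant k is returned; if
#' none is significant (no stable structure beyond the minimum), the smallest
#' assessed k is.
#'
#' @param result an `hf_consensus`.
#' @param delta_threshold absolute delta-area floor (default 0.05).
#' @param gain_ratio required dominance over the mean remaining delta-areas
#'   (default 5).
#' @return the selected k (integer).
#' @export
select_k <- function(result, delta_threshold = 0.05, gain_ratio = 5) {
  cc <- consensus_cdf(result)
  ks <- result$k_range
  if (length(ks) < 2) return(ks[1])
  delta <- cc$delta_area
  best <- ks[1]
  for (i in seq_len(length(ks) - 1)) {
    tail_mean <- mean(delta[(i + 1):length(ks)])
    if (delta[i] >= delta_threshold && delta[i] >= gain_ratio * tail_mean)
      best <- ks[i]
  }
  best
}

#' Flag patients whose images cluster away from their labeled class
#'
#' Clusters at the selected k are annotated by class concentration: the
#' cluster receiving the plurality of failing-labeled images is the failing
#' cluster, the one receiving the plurality of non-failing-labeled images is
#' the non-failing cluster, and every other cluster is "intermediate" (a
#' mislabeled severe-pathology group forms a small cluster of its own whose
#' member labels alone would not reveal it).  A patient labeled non-failing
#' is flagged when the majority of its images sit in the failing cluster or
#' in an intermediate cluster.
#'
#' @param result an `hf_consensus` built with `item_patients`.
#' @param labels named character vector: patient id -> label.
#' @param k cluster number (default: [select_k()]).
#' @return character vector of flagged patient ids (possibly empty).
#' @export
flag_discordant_patients <- function(result, labels, k = NULL) {
  if (is.null(result$item_patients))
    stop_invalid_argument("consensus result lacks item -> patient mapping")
  if (is.null(k)) k <- select_k(result)
  ct <- result$assignments[[as.character(k)]]
  if (is.null(ct)) stop_invalid_argument("k was not assessed")
  item_lab <- labels[result$item_patients]
  pos_levels <- c("failing", "abnormal_or_heart_failure")
  is_pos <- item_lab %in% pos_levels
  clusters <- sort(unique(ct))
  for (cl in clusters) {
    if (sum(ct == cl) == 0)
      warning(sprintf("cluster %d is empty and was skipped", cl), call. = FALSE)
  }
  pos_share <- vapply(clusters, function(cl) sum(ct == cl & is_pos), 0)
  neg_share <- vapply(clusters, function(cl) sum(ct == cl & !is_pos), 0)
  status <- rep("intermediate", length(clusters))
  names(status) <- as.character(clusters)
  if (any(pos_share > 0)) status[which.max(pos_share)] <- "failing"
  if (any(neg_share > 0)) {
    nf_home <- which.max(neg_share)
    if (status[nf_home] == "failing") {
      # both classes concentrate in one cluster: fall back to its majority
      status[nf_home] <- if (pos_share[nf_home] >= neg_share[nf_home])
        "failing" else "non_failing"
    } else {
      status[nf_home] <- "non_failing"
    }
  }
  flagged <- character(0)
  for (pid in unique(result$item_patients)) {
    if (labels[pid] %in% pos_levels) next  # only non-failing-labeled patients
    st <- status[as.character(ct[result$item_patients == pid])]
    if (mean(st %in% c("failing", "intermediate")) > 0.5)
      flagged <- c(flagged, pid)
  }
  sort(flagged)
}
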