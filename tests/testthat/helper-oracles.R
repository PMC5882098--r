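# Independent brute-force oracles used across the suite.  These deliberately
# re-derive quantities from first principles (loops, enumeration, rank sums)
# and never call the implementation paths they check.

# nearest-palette-center pixel classifier: returns the fraction of pixels
# whose nearest anchor is the stroma color
measured_stroma_fraction <- function(pixels) {
  pal <- hf_palette()
  centers <- do.call(rbind, pal)
  px <- cbind(as.numeric(pixels[, , 1]), as.numeric(pixels[, , 2]),
              as.numeric(pixels[, , 3]))
  best <- rep(1L, nrow(px)); bestd <- rep(Inf, nrow(px))
  for (i in seq_len(nrow(centers))) {
    d <- (px[, 1] - centers[i, 1])^2 + (px[, 2] - centers[i, 2])^2 +
      (px[, 3] - centers[i, 3])^2
    hit <- d < bestd
    best[hit] <- i; bestd[hit] <- d[hit]
  }
  mean(rownames(centers)[best] == "stroma")
}

# exhaustive Otsu: try all 255 cut points, maximize between-class variance,
# lowest gray level on ties
otsu_brute_force <- function(counts) {
  n <- sum(counts)
  levels <- 0:255
  best_t <- NA_integer_; best_v <- -Inf
  for (t in 0:254) {
    w0 <- sum(counts[1:(t + 1)]) / n
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(levels[1:(t + 1)] * counts[1:(t + 1)]) / sum(counts[1:(t + 1)])
    mu1 <- sum(levels[(t + 2):256] * counts[(t + 2):256]) /
      sum(counts[(t + 2):256])
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best_v + 1e-12) { best_v <- v; best_t <- t }
  }
  best_t
}

# tie-corrected rank-sum AUC: U / (n1 * n2) with midranks
auc_rank_oracle <- function(scores, truth) {
  r <- rank(scores, ties.method = "average")
  n1 <- sum(truth); n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# exhaustive greedy mRMR with the same discretization, re-implemented with
# plain loops (no shared code path with mrmr_select)
mrmr_brute_force <- function(X, y, k) {
  disc <- apply(X, 2, function(col) {
    m <- mean(col); s <- stats::sd(col)
    if (!is.finite(s) || s == 0) return(rep(1L, length(col)))
    1L + (col > m - s / 2) + (col > m + s / 2)
  })
  mi <- function(a, b) {
    tab <- table(a, b); p <- tab / sum(tab)
    px <- rowSums(p); py <- colSums(p)
    tot <- 0
    for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
      if (p[i, j] > 0) tot <- tot + p[i, j] * log(p[i, j] / (px[i] * py[j]))
    tot
  }
  yf <- as.integer(factor(y))
  p <- ncol(X)
  rel <- sapply(seq_len(p), function(j) mi(disc[, j], yf))
  sel <- integer(0)
  for (step in seq_len(k)) {
    best <- NA_integer_; best_c <- -Inf
    for (j in seq_len(p)) {
      if (j %in% sel) next
      red <- if (length(sel)) mean(sapply(sel, function(s2) mi(disc[, j], disc[, s2]))) else 0
      cr <- rel[j] - red
      if (cr > best_c + 1e-12) { best_c <- cr; best <- j }
    }
    sel <- c(sel, best)
  }
  sel
}

# brute-force consensus matrices: replay the implementation's seeded
# subsample/clustering draws, then count co-memberships with nested loops
consensus_brute_force <- function(features, k_range, n_resamples,
                                  item_fraction, rng_seed) {
  n <- nrow(features)
  sds <- apply(features, 2, stats::sd)
  sds[!is.finite(sds) | sds == 0] <- 1
  Z <- sweep(sweep(features, 2, colMeans(features)), 2, sds, "/")
  m <- ceiling(item_fraction * n)
  co <- lapply(k_range, function(k) matrix(0, n, n))
  inc <- matrix(0, n, n)
  withr::with_seed(as.integer(rng_seed), {
    for (r in seq_len(n_resamples)) {
      sub <- sort(sample.int(n, m))
      for (a in sub) for (b in sub) inc[a, b] <- inc[a, b] + 1
      hc <- stats::hclust(stats::dist(Z[sub, , drop = FALSE]), method = "average")
      for (ki in seq_along(k_range)) {
        ct <- stats::cutree(hc, k = k_range[ki])
        for (ia in seq_along(sub)) for (ib in seq_along(sub)) {
          if (ct[ia] == ct[ib])
            co[[ki]][sub[ia], sub[ib]] <- co[[ki]][sub[ia], sub[ib]] + 1
        }
      }
    }
  })
  lapply(seq_along(k_range), function(ki) {
    M <- co[[ki]] / inc
    M[inc == 0] <- NA_real_
    diag(M) <- 1
    M
  })
}

# quick separable patch fixture: dark vs light 64-px patches
separable_patches <- function(n_per_class = 100, seed = 1) {
  withr::with_seed(seed, {
    arrs <- array(as.raw(0), c(64, 64, 3, 2 * n_per_class))
    for (i in seq_len(n_per_class)) {
      arrs[, , , i] <- as.raw(30 + sample(0:20, 64 * 64 * 3, TRUE))
      arrs[, , , n_per_class + i] <- as.raw(170 + sample(0:20, 64 * 64 * 3, TRUE))
    }
    meta <- data.frame(
      patient_id = rep(c("PF", "PN"), each = n_per_class),
      roi_id = "r", row = 0L, col = 0L, orientation = 0L,
      label = rep(c("failing", "non_failing"), each = n_per_class),
      stringsAsFactors = FALSE)
    hfhisto:::patch_set(arrs, meta, 64L)
  })
}

# small ready-made slide + full-tissue mask
toy_slide <- function(side = 256, val = 120) {
  px <- array(as.integer(val), c(side, side, 3))
  slide_image(px, mpp = 2, slide_id = "toy")
}

full_mask <- function(slide) {
  structure(list(mask = matrix(TRUE, dim(slide$pixels)[1], dim(slide$pixels)[2]),
                 threshold_used = 128L, provenance = "otsu"),
            class = "hf_mask")
}
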