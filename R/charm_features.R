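# Engineered texture-feature bank (CHARM-style comparator arm).
#
# A documented ~330-feature subset of the classic engineered-feature families:
# per-channel (gray, R, G, B) pixel statistics, quantiles, Haralick
# co-occurrence statistics, local binary patterns, edge statistics, Chebyshev
# polynomial coefficient statistics and spectral-magnitude statistics, plus
# gray-only Gabor filter-bank energies and Zernike moment magnitudes.  Every
# feature is deterministic and named.

# ---- Haralick co-occurrence statistics --------------------------------------

# gray-level co-occurrence matrix for one (dr, dc) offset, symmetric,
# normalized; `q` is an integer matrix of levels 1..nlev
glcm <- function(q, nlev, dr, dc) {
  h <- nrow(q); w <- ncol(q)
  r0 <- max(1, 1 - dr); r1 <- min(h, h - dr)
  c0 <- max(1, 1 - dc); c1 <- min(w, w - dc)
  a <- q[r0:r1, c0:c1]
  b <- q[(r0 + dr):(r1 + dr), (c0 + dc):(c1 + dc)]
  counts <- tabulate((a - 1L) * nlev + b, nbins = nlev * nlev)
  P <- matrix(counts, nlev, nlev, byrow = TRUE)
  P <- P + t(P)
  P / sum(P)
}

haralick_stats <- function(P) {
  nlev <- nrow(P)
  i <- matrix(seq_len(nlev), nlev, nlev)
  j <- t(i)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(nlev) * px); muy <- sum(seq_len(nlev) * py)
  sdx <- sqrt(sum((seq_len(nlev) - mux)^2 * px))
  sdy <- sqrt(sum((seq_len(nlev) - muy)^2 * py))
  # p_{x+y} over k = 2..2n and p_{x-y} over d = 0..n-1
  ksum <- as.vector(tapply(P, i + j, sum))
  kvals <- sort(unique(as.vector(i + j)))
  dsum <- as.vector(tapply(P, abs(i - j), sum))
  dvals <- sort(unique(as.vector(abs(i - j))))
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  asm <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  correlation <- if (sdx > 0 && sdy > 0)
    (sum(i * j * P) - mux * muy) / (sdx * sdy) else 0
  variance <- sum((i - mux)^2 * P)
  idm <- sum(P / (1 + (i - j)^2))
  sum_avg <- sum(kvals * ksum)
  sum_var <- sum((kvals - sum_avg)^2 * ksum)
  sum_ent <- ent(ksum)
  entropy <- ent(P)
  diff_avg <- sum(dvals * dsum)
  diff_var <- sum((dvals - diff_avg)^2 * dsum)
  diff_ent <- ent(dsum)
  hx <- ent(px); hy <- ent(py)
  pxy <- outer(px, py)
  hxy1 <- { m <- pxy[P > 0]; -sum(P[P > 0] * log(m[m > 0])) }
  hxy2 <- ent(pxy)
  icm1 <- if (max(hx, hy) > 0) (entropy - hxy1) / max(hx, hy) else 0
  icm2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))
  c(asm = asm, contrast = contrast, correlation = correlation,
    variance = variance, idm = idm, sum_avg = sum_avg, sum_var = sum_var,
    sum_ent = sum_ent, entropy = entropy, diff_var = diff_var,
    diff_ent = diff_ent, icm1 = icm1, icm2 = icm2)
}

haralick_features <- function(chan, nlev = 32L) {
  rng <- range(chan)
  if (rng[2] > rng[1]) {
    q <- 1L + floor((chan - rng[1]) / (rng[2] - rng[1]) * nlev)
    q[q > nlev] <- nlev
  } else {
    q <- matrix(1L, nrow(chan), ncol(chan))
  }
  storage.mode(q) <- "integer"
  offs <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  stats <- sapply(offs, function(o) haralick_stats(glcm(q, nlev, o[1], o[2])))
  rowMeans(stats)
}

# ---- local binary patterns (rotation-invariant uniform, 8 neighbours) -------

lbp_features <- function(chan) {
  h <- nrow(chan); w <- ncol(chan)
  if (h < 3 || w < 3) return(stats::setNames(rep(0, 10), paste0("lbp", 0:9)))
  ctr <- chan[2:(h - 1), 2:(w - 1)]
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  bits <- lapply(offs, function(o)
    chan[(2 + o[1]):(h - 1 + o[1]), (2 + o[2]):(w - 1 + o[2])] >= ctr)
  ones <- Reduce(`+`, bits)
  trans <- Reduce(`+`, lapply(seq_along(bits), function(k)
    bits[[k]] != bits[[if (k == 8) 1 else k + 1]]))
  code <- ifelse(trans <= 2, ones, 9L)  # riu2: 0..8 uniform, 9 non-uniform
  counts <- tabulate(code + 1L, nbins = 10L)
  stats::setNames(counts / sum(counts), paste0("lbp", 0:9))
}

# ---- edge statistics --------------------------------------------------------

edge_features <- function(chan) {
  h <- nrow(chan); w <- ncol(chan)
  if (h < 3 || w < 3) return(c(grad_mean = 0, grad_sd = 0, edge_density = 0))
  gx <- chan[2:(h - 1), 3:w] - chan[2:(h - 1), 1:(w - 2)]
  gy <- chan[3:h, 2:(w - 1)] - chan[1:(h - 2), 2:(w - 1)]
  mag <- sqrt(gx^2 + gy^2)
  m <- mean(mag); s <- stats::sd(mag)
  c(grad_mean = m, grad_sd = ifelse(is.finite(s), s, 0),
    edge_density = mean(mag > 2 * m))
}

# ---- Chebyshev polynomial coefficients --------------------------------------

cheb_matrix <- function(n, order) {
  x <- seq(-1, 1, length.out = n)
  T <- matrix(0, n, order + 1)
  T[, 1] <- 1
  if (order >= 1) T[, 2] <- x
  for (k in 3:(order + 1)) T[, k] <- 2 * x * T[, k - 1] - T[, k - 2]
  # discrete orthogonality normalization (least-squares projection)
  sweep(T, 2, colSums(T^2), "/")
}

chebyshev_features <- function(chan, order = 20L, side = 64L) {
  g <- as.matrix(EBImage::resize(chan, w = side, h = side))
  g <- g - mean(g)  # DC carried by the pixel statistics, not the polynomials
  T <- cheb_matrix(side, order)
  C <- t(T) %*% g %*% T  # coefficient matrix (order+1 x order+1)
  tot <- outer(0:order, 0:order, `+`)
  keep <- tot <= order & tot > 0  # upper-triangular band, DC excluded
  coef <- C[keep]
  band <- vapply(1:order, function(k) sqrt(mean(C[tot == k]^2)), 0)
  out <- c(moment_stats(coef),
           stats::quantile(coef, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE),
           band)
  names(out) <- c("coef_mean", "coef_sd", "coef_skew", "coef_kurtosis",
                  paste0("coef_q", c(10, 25, 50, 75, 90)),
                  paste0("band", 1:order))
  out
}

# ---- spectral magnitude -----------------------------------------------------

spectral_features <- function(chan) {
  mag <- log1p(Mod(stats::fft(chan)))
  mag <- mag[-1]  # drop the DC term so a constant image scores zero
  out <- c(moment_stats(mag),
           stats::quantile(mag, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE))
  names(out) <- c("mean", "sd", "skew", "kurtosis",
                  paste0("q", c(10, 25, 50, 75, 90)))
  out
}

# ---- Gabor filter-bank energies (gray only) ---------------------------------

gabor_kernel <- function(freq, theta, phase) {
  sigma <- 0.56 / freq
  half <- min(15L, ceiling(2.5 * sigma))
  xy <- seq(-half, half)
  X <- matrix(xy, length(xy), length(xy), byrow = TRUE)
  Y <- matrix(xy, length(xy), length(xy))
  xr <- X * cos(theta) + Y * sin(theta)
  yr <- -X * sin(theta) + Y * cos(theta)
  env <- exp(-(xr^2 + yr^2) / (2 * sigma^2))
  env * cos(2 * pi * freq * xr + phase)
}

gabor_features <- function(gray) {
  freqs <- c(0.05, 0.1, 0.2, 0.4)
  thetas <- c(0, 45, 90, 135) * pi / 180
  g <- gray - mean(gray)
  out <- numeric(0)
  for (f in freqs) for (th in thetas) {
    re <- EBImage::filter2(g, gabor_kernel(f, th, 0))
    im <- EBImage::filter2(g, gabor_kernel(f, th, pi / 2))
    out <- c(out, mean(re^2 + im^2))
  }
  names(out) <- paste0("gabor_f", rep(freqs, each = 4), "_t",
                       rep(c(0, 45, 90, 135), 4))
  out
}

# ---- Zernike moment magnitudes (gray only) ----------------------------------

zernike_radial <- function(n, m, rho) {
  out <- 0
  for (s in 0:((n - m) / 2)) {
    out <- out + (-1)^s * factorial(n - s) /
      (factorial(s) * factorial((n + m) / 2 - s) * factorial((n - m) / 2 - s)) *
      rho^(n - 2 * s)
  }
  out
}

# basis cached in the package namespace (deterministic, order/side fixed)
the <- new.env(parent = emptyenv())

zernike_basis <- function(side = 64L, max_order = 8L) {
  key <- sprintf("zernike_%d_%d", side, max_order)
  if (!is.null(the[[key]])) return(the[[key]])
  xy <- (seq_len(side) - (side + 1) / 2) / (side / 2)
  X <- matrix(xy, side, side, byrow = TRUE)
  Y <- matrix(xy, side, side)
  rho <- sqrt(X^2 + Y^2)
  theta <- atan2(Y, X)
  disk <- rho <= 1
  basis <- list()
  for (n in 0:max_order) for (m in seq(n %% 2, n, by = 2)) {
    R <- zernike_radial(n, m, rho)
    V <- complex(real = R * cos(m * theta), imaginary = -R * sin(m * theta))
    V[!disk] <- 0
    basis[[sprintf("zern_n%d_m%d", n, m)]] <- V * (n + 1) / pi
  }
  the[[key]] <- list(basis = basis, n_disk = sum(disk))
  the[[key]]
}

zernike_features <- function(gray, side = 64L, max_order = 8L) {
  g <- as.matrix(EBImage::resize(gray, w = side, h = side)) / 255
  zb <- zernike_basis(side, max_order)
  vapply(zb$basis, function(V) Mod(sum(g * V)) / zb$n_disk, 0)
}

# ---- the assembled bank -----------------------------------------------------

channel_features <- function(chan) {
  v <- as.vector(chan)
  out <- c(moment_stats(v),
           stats::quantile(v, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE))
  names(out) <- c("mean", "sd", "skew", "kurtosis",
                  paste0("q", c(10, 25, 50, 75, 90)))
  har <- haralick_features(chan); names(har) <- paste0("har_", names(har))
  sp <- spectral_features(chan); names(sp) <- paste0("fft_", names(sp))
  ch <- chebyshev_features(chan); names(ch) <- paste0("cheb_", names(ch))
  c(out, har, lbp_features(chan), edge_features(chan), ch, sp)
}

#' Extract the engineered feature vector of an ROI
#'
#' Computes a deterministic, named, ~330-element texture-feature vector:
#' on each of the gray, red, green and blue channels the pixel moments
#' (mean, sd, skewness, excess kurtosis), five quantiles, 13 Haralick
#' co-occurrence statistics averaged over 4 offsets, a 10-bin
#' rotation-invariant uniform local-binary-pattern histogram, edge statistics,
#' Chebyshev polynomial coefficient statistics (order <= 20) and statistics of
#' the spectral (Fourier) magnitude; plus, on gray only, 16 Gabor filter-bank
#' energies (4 frequencies x 4 orientations) and 25 Zernike moment magnitudes
#' (order <= 8).
#'
#' @param roi an `hf_roi` (8-bit RGB raster).
#' @return named numeric vector (identical length and name order for any
#'   input size).
#' @export
extract_features <- function(roi) {
  if (!inherits(roi, "hf_roi")) stop_invalid_argument("`roi` must be an hf_roi")
  px <- roi$pixels
  if (length(dim(px)) != 3L || dim(px)[3] != 3L || any(dim(px)[1:2] < 8))
    stop_invalid_argument("ROI raster must be RGB and at least 8 x 8")
  chans <- list(gray = rgb_to_gray(px),
                R = px[, , 1] * 1.0, G = px[, , 2] * 1.0, B = px[, , 3] * 1.0)
  out <- numeric(0)
  for (nm in names(chans)) {
    f <- channel_features(chans[[nm]])
    names(f) <- paste0(nm, "_", names(f))
    out <- c(out, f)
  }
  out <- c(out, gabor_features(chans$gray), zernike_features(chans$gray))
  out[!is.finite(out)] <- 0
  out
}

#' Extract the feature matrix of a set of ROIs
#'
#' @param rois list of `hf_roi` (or an `hf_cohort`, whose ROIs are used).
#' @return matrix (one row per ROI, named columns) with attributes `roi_id`
#'   and `patient_id`.
#' @export
extract_feature_matrix <- function(rois) {
  if (inherits(rois, "hf_cohort")) rois <- rois$rois
  rows <- lapply(rois, extract_features)
  X <- do.call(rbind, rows)
  rownames(X) <- vapply(rois, `[[`, "", "roi_id")
  attr(X, "patient_id") <- vapply(rois, `[[`, "", "patient_id")
  X
}
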