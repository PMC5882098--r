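# Slide-level preparation: tissue masking and ROI sampling.
#
# A slide is masked by Otsu thresholding of its grayscale conversion (tissue
# is darker than the glass background), small objects and holes are removed,
# and square non-overlapping regions of interest are drawn at random from
# within the mask by seeded rejection sampling.

#' Construct a slide image
#'
#' @param pixels integer array of dim `c(h, w, 3)`, 8-bit RGB.
#' @param mpp microns per pixel (positive).
#' @param slide_id identifier.
#' @return object of class `hf_slide`.
#' @export
slide_image <- function(pixels, mpp, slide_id = "slide") {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L || any(dim(pixels)[1:2] < 1))
    stop_invalid_argument("`pixels` must be a non-empty h x w x 3 RGB array")
  if (!is.numeric(mpp) || length(mpp) != 1L || mpp <= 0)
    stop_invalid_argument("`mpp` must be a positive number")
  structure(list(pixels = pixels, mpp = mpp, slide_id = as.character(slide_id)),
            class = "hf_slide")
}

#' @export
print.hf_slide <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<hf_slide '%s'> %d x %d px at %.3g um/px (%.2f x %.2f mm)\n",
              x$slide_id, d[1], d[2], x$mpp,
              d[1] * x$mpp / 1000, d[2] * x$mpp / 1000))
  invisible(x)
}

#' Region of interest
#'
#' @param pixels integer array `side_px x side_px x 3`.
#' @param patient_id,roi_id identifiers.
#' @param row,col 0-based top-left corner in slide coordinates (half-open
#'   rectangles, row-major).
#' @return object of class `hf_roi`.
#' @export
region_of_interest <- function(pixels, patient_id = NA_character_,
                               roi_id = "roi", row = 0L, col = 0L) {
  d <- dim(pixels)
  if (length(d) != 3L || d[1] != d[2] || d[3] != 3L)
    stop_invalid_argument("ROI `pixels` must be a square s x s x 3 RGB array")
  structure(list(pixels = pixels, patient_id = as.character(patient_id),
                 roi_id = as.character(roi_id), row = as.integer(row),
                 col = as.integer(col), side_px = d[1]),
            class = "hf_roi")
}

# ---- resampling -------------------------------------------------------------

# 1-D area-averaging weight matrix mapping n_in source pixels onto n_out
# output pixels; each output pixel averages the source interval it covers
# (exact block mean for integer factors, length-weighted overlap otherwise).
area_weights <- function(n_in, n_out) {
  f <- n_in / n_out
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    a <- (i - 1) * f
    b <- i * f
    k0 <- floor(a) + 1
    k1 <- min(n_in, ceiling(b))
    for (k in k0:k1) {
      ov <- min(b, k) - max(a, k - 1)
      if (ov > 0) W[i, k] <- ov / f
    }
  }
  W
}

#' Downsample a slide to a target resolution
#'
#' Area-averaging resampler: each output pixel is the mean of the source area
#' it covers, so constant regions are conserved exactly.  Upsampling is
#' refused.
#'
#' @param slide an `hf_slide`.
#' @param target_mpp target microns per pixel; must be `>= slide$mpp`.
#' @return an `hf_slide` at `target_mpp`; the identical object when
#'   `target_mpp == slide$mpp`.
#' @export
downsample_to_target <- function(slide, target_mpp) {
  if (!inherits(slide, "hf_slide"))
    stop_invalid_argument("`slide` must be an hf_slide")
  if (!is.numeric(target_mpp) || length(target_mpp) != 1L || target_mpp <= 0)
    stop_invalid_argument("`target_mpp` must be a positive number")
  if (target_mpp < slide$mpp)
    stop_invalid_argument("upsampling is not supported: target_mpp < slide mpp")
  if (target_mpp == slide$mpp) return(slide)
  d <- dim(slide$pixels)
  scale <- slide$mpp / target_mpp
  h_out <- max(1L, floor(d[1] * scale))
  w_out <- max(1L, floor(d[2] * scale))
  Wr <- area_weights(d[1], h_out)
  Wc <- area_weights(d[2], w_out)
  out <- array(0, dim = c(h_out, w_out, 3))
  for (ch in 1:3) out[, , ch] <- Wr %*% slide$pixels[, , ch] %*% t(Wc)
  slide_image(as_raster8(out), mpp = target_mpp, slide_id = slide$slide_id)
}

# ---- Otsu masking -----------------------------------------------------------

#' Otsu threshold of an 8-bit histogram
#'
#' Returns the gray level `t` in 0..254 maximizing the between-class variance
#' of the split `gray <= t` vs `gray > t`, computed over all 256 levels.
#' Ties are broken toward the lowest maximizing level.
#'
#' @param counts integer vector of length 256 (counts of gray levels 0..255).
#' @return the threshold (single integer gray level).
#' @export
otsu_threshold <- function(counts) {
  if (length(counts) != 256L || any(counts < 0))
    stop_invalid_argument("`counts` must be 256 non-negative bin counts")
  n <- sum(counts)
  if (n == 0) stop_degenerate_input("empty histogram")
  levels <- 0:255
  p <- counts / n
  w0 <- cumsum(p)                      # P(gray <= t), t = 0..255
  mu_t <- cumsum(p * levels)           # partial first moment
  mu <- mu_t[256]
  w1 <- 1 - w0
  # between-class variance at each candidate t = 0..254
  valid <- w0[1:255] > 0 & w1[1:255] > 0
  if (!any(valid))
    stop_degenerate_input("constant-intensity input: no valid Otsu threshold")
  num <- (mu * w0[1:255] - mu_t[1:255])^2
  bcv <- rep(-Inf, 255)
  bcv[valid] <- num[valid] / (w0[1:255][valid] * w1[1:255][valid])
  which.max(bcv) - 1L                  # which.max takes the first (lowest) tie
}

#' Compute a tissue mask for a slide
#'
#' Converts the slide to grayscale (Rec. 601 luma), applies Otsu thresholding
#' (tissue = the darker side), removes connected foreground objects smaller
#' than `min_object_mm2` and fills holes.
#'
#' @param slide an `hf_slide`.
#' @param min_object_mm2 minimum object area retained, in square millimetres
#'   (default 0.1).
#' @return object of class `hf_mask` with fields `mask` (logical matrix),
#'   `threshold_used`, `provenance`.
#' @export
compute_tissue_mask <- function(slide, min_object_mm2 = 0.1) {
  if (!inherits(slide, "hf_slide"))
    stop_invalid_argument("`slide` must be an hf_slide")
  gray <- rgb_to_gray(slide$pixels)
  g8 <- pmin(255L, pmax(0L, as.integer(round(gray))))
  counts <- tabulate(g8 + 1L, nbins = 256L)
  thr <- otsu_threshold(counts)
  fg <- matrix(g8 <= thr, nrow(gray), ncol(gray))
  # remove small objects (< min_object_mm2 at this mpp)
  min_px <- min_object_mm2 * 1e6 / slide$mpp^2
  lab <- EBImage::bwlabel(fg * 1)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_px)
    fg <- matrix(lab %in% keep, nrow(gray), ncol(gray))
  }
  # fill holes
  fg <- EBImage::fillHull(fg * 1) > 0
  if (!any(fg))
    stop_degenerate_input("no tissue object survives masking")
  structure(list(mask = fg, threshold_used = thr, provenance = "otsu"),
            class = "hf_mask")
}

#' Apply manual edits to a tissue mask
#'
#' The manual-refinement step is represented as edit layers: foreground
#' becomes `(mask | additions) & !removals`.
#'
#' @param mask an `hf_mask`.
#' @param additions,removals logical matrices congruent with the mask, or
#'   `NULL` for no edit.
#' @return an `hf_mask` with provenance `"otsu+manual"`.
#' @export
refine_mask <- function(mask, additions = NULL, removals = NULL) {
  if (!inherits(mask, "hf_mask"))
    stop_invalid_argument("`mask` must be an hf_mask")
  m <- mask$mask
  for (layer in list(additions, removals)) {
    if (!is.null(layer) && !identical(dim(layer), dim(m)))
      stop_invalid_argument("edit layer dimensions must match the mask")
  }
  if (!is.null(additions)) m <- m | (additions > 0)
  if (!is.null(removals)) m <- m & !(removals > 0)
  if (!any(m))
    stop_degenerate_input("refinement removed all foreground")
  structure(list(mask = m, threshold_used = mask$threshold_used,
                 provenance = "otsu+manual"),
            class = "hf_mask")
}

# ---- ROI sampling -----------------------------------------------------------

#' Sample non-overlapping ROIs from within a tissue mask
#'
#' Positions are drawn by seeded rejection sampling: a candidate top-left
#' corner is accepted when its square contains at least `min_tissue_fraction`
#' tissue pixels and does not intersect any previously accepted ROI.
#'
#' @param slide an `hf_slide`.
#' @param mask an `hf_mask` congruent with the slide.
#' @param n number of ROIs (default 11, the per-patient sampling depth).
#' @param side_px ROI side in pixels (default 1250, i.e. 2.5 mm at 2 um/px).
#' @param min_tissue_fraction minimum tissue-pixel fraction per ROI
#'   (default 0.9).
#' @param rng_seed integer seed.
#' @param max_attempts rejection-sampling budget (default 10000).
#' @param patient_id identifier propagated into the ROIs.
#' @return list of `hf_roi` objects of length `n`.
#' @export
sample_rois <- function(slide, mask, n = 11, side_px = 1250,
                        min_tissue_fraction = 0.9, rng_seed = 1L,
                        max_attempts = 10000, patient_id = NA_character_) {
  if (!inherits(slide, "hf_slide")) stop_invalid_argument("`slide` must be an hf_slide")
  if (!inherits(mask, "hf_mask")) stop_invalid_argument("`mask` must be an hf_mask")
  n <- check_count(n, "n")
  side_px <- check_count(side_px, "side_px")
  check_proportion(min_tissue_fraction, "min_tissue_fraction")
  d <- dim(slide$pixels)
  if (!identical(dim(mask$mask), d[1:2]))
    stop_invalid_argument("mask dimensions must match the slide")
  if (side_px > min(d[1:2]))
    stop_invalid_argument("`side_px` exceeds the slide dimensions")
  # summed-area table of the mask for O(1) tissue-fraction queries
  cs <- apply(mask$mask * 1, 2, cumsum)        # cumulative down rows
  sat <- matrix(0, d[1] + 1, d[2] + 1)
  sat[-1, -1] <- t(apply(cs, 1, cumsum))       # then across columns
  rect_sum <- function(r0, c0, s) {
    sat[r0 + s + 1, c0 + s + 1] - sat[r0 + 1, c0 + s + 1] -
      sat[r0 + s + 1, c0 + 1] + sat[r0 + 1, c0 + 1]
  }
  need <- min_tissue_fraction * side_px^2
  placed <- list()
  coords <- matrix(0L, 0, 2)
  withr::with_seed(as.integer(rng_seed), {
    attempts <- 0L
    while (length(placed) < n && attempts < max_attempts) {
      attempts <- attempts + 1L
      r0 <- sample.int(d[1] - side_px + 1L, 1L) - 1L  # 0-based top-left
      c0 <- sample.int(d[2] - side_px + 1L, 1L) - 1L
      if (rect_sum(r0, c0, side_px) < need) next
      if (nrow(coords) > 0) {
        overlap <- any(abs(coords[, 1] - r0) < side_px &
                         abs(coords[, 2] - c0) < side_px)
        if (overlap) next
      }
      coords <- rbind(coords, c(r0, c0))
      placed[[length(placed) + 1L]] <- region_of_interest(
        slide$pixels[(r0 + 1):(r0 + side_px), (c0 + 1):(c0 + side_px), ,
                     drop = FALSE],
        patient_id = patient_id,
        roi_id = sprintf("%s_roi%02d", slide$slide_id, length(placed) + 1L),
        row = r0, col = c0)
    }
  })
  if (length(placed) < n)
    stop_capacity(sprintf(
      "could only place %d of %d ROIs within the attempt budget",
      length(placed), n), placed = length(placed), requested = n)
  placed
}
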