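# Patch sampling and right-angle rotation augmentation.
#
# Patches are the CNN's training and inference currency: 64 x 64 px RGB tiles
# (128 x 128 um at 2 um/px) carrying the label of the patient they came from
# (weak supervision).  Patch rasters are stored as a raw array of dim
# (patch_px, patch_px, 3, n) to keep large training sets at one byte per
# channel value.

patch_set <- function(pixels, meta, patch_px) {
  structure(list(pixels = pixels, meta = meta, patch_px = as.integer(patch_px)),
            class = "hf_patches")
}

#' Number of patches in a patch set
#' @param ps an `hf_patches` object.
#' @return integer count.
#' @export
n_patches <- function(ps) nrow(ps$meta)

#' @export
print.hf_patches <- function(x, ...) {
  cat(sprintf("<hf_patches> %d patches of %d px; labels: %s\n",
              n_patches(x), x$patch_px,
              paste(names(table(x$meta$label)), table(x$meta$label),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

# extract one patch (integer array) from a raw patch array
patch_pixels <- function(ps, i) {
  p <- ps$patch_px
  arr <- ps$pixels[, , , i, drop = FALSE]
  dim(arr) <- c(p, p, 3)
  storage.mode(arr) <- "integer"
  arr
}

#' Sample labeled patches from an ROI
#'
#' Draws `n` patch offsets uniformly at random (with replacement; overlap
#' between patches is permitted), all at orientation 0.
#'
#' @param roi an `hf_roi`.
#' @param label label propagated to every patch (the ROI's patient label).
#' @param n number of patches (default 100, the per-ROI training depth).
#' @param patch_px patch side in pixels (default 64).
#' @param rng_seed integer seed.
#' @return an `hf_patches` object with `n` patches.
#' @export
sample_patches <- function(roi, label = NA_character_, n = 100, patch_px = 64,
                           rng_seed = 1L) {
  if (!inherits(roi, "hf_roi")) stop_invalid_argument("`roi` must be an hf_roi")
  if (!is.numeric(n) || n < 0 || n != floor(n))
    stop_invalid_argument("`n` must be a non-negative integer")
  patch_px <- check_count(patch_px, "patch_px")
  if (patch_px > roi$side_px)
    stop_invalid_argument("`patch_px` exceeds the ROI side")
  n <- as.integer(n)
  max_off <- roi$side_px - patch_px  # offsets are 0-based in [0, side - patch]
  off <- withr::with_seed(as.integer(rng_seed), {
    cbind(sample.int(max_off + 1L, n, replace = TRUE) - 1L,
          sample.int(max_off + 1L, n, replace = TRUE) - 1L)
  })
  pixels <- array(as.raw(0), dim = c(patch_px, patch_px, 3L, n))
  for (i in seq_len(n)) {
    r0 <- off[i, 1]; c0 <- off[i, 2]
    tile <- roi$pixels[(r0 + 1):(r0 + patch_px), (c0 + 1):(c0 + patch_px), ,
                       drop = FALSE]
    pixels[, , , i] <- as.raw(tile)
  }
  meta <- data.frame(
    patient_id = rep(roi$patient_id, n), roi_id = rep(roi$roi_id, n),
    row = if (n) off[, 1] else integer(0),
    col = if (n) off[, 2] else integer(0),
    orientation = rep(0L, n), label = rep(as.character(label), n),
    stringsAsFactors = FALSE)
  patch_set(pixels, meta, patch_px)
}

# 90-degree counterclockwise rotation of an (p, p, 3) array
rotate90 <- function(a) {
  p <- dim(a)[1]
  aperm(a, c(2, 1, 3))[p:1, , , drop = FALSE]
}

#' Right-angle rotation augmentation
#'
#' Expands a patch set four-fold: for each input patch the output contains
#' the orientations 0, 90, 180 and 270 degrees, with labels and provenance
#' preserved.  Augmentation is a training-time operation only; inference
#' never uses it.
#'
#' @param ps an `hf_patches` object.
#' @return an `hf_patches` object with `4 * n_patches(ps)` patches (all
#'   originals first, then the 90, 180 and 270 degree copies).
#' @export
augment_rotations <- function(ps) {
  if (!inherits(ps, "hf_patches")) stop_invalid_argument("`ps` must be hf_patches")
  n <- n_patches(ps)
  p <- ps$patch_px
  out <- array(as.raw(0), dim = c(p, p, 3L, 4L * n))
  if (n > 0) {
    out[, , , seq_len(n)] <- ps$pixels
    for (i in seq_len(n)) {
      a <- ps$pixels[, , , i, drop = FALSE]
      dim(a) <- c(p, p, 3L)
      a <- rotate90(a); out[, , , n + i] <- a
      a <- rotate90(a); out[, , , 2L * n + i] <- a
      a <- rotate90(a); out[, , , 3L * n + i] <- a
    }
  }
  meta <- ps$meta[rep(seq_len(n), times = 4L), , drop = FALSE]
  meta$orientation <- rep(c(0L, 90L, 180L, 270L), each = n)
  rownames(meta) <- NULL
  patch_set(out, meta, p)
}

#' Concatenate patch sets
#'
#' @param ... `hf_patches` objects (or one list of them) with equal patch
#'   sizes.
#' @return a single `hf_patches` object.
#' @export
bind_patches <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1]], "hf_patches"))
    sets <- sets[[1]]
  sizes <- vapply(sets, function(s) s$patch_px, 1L)
  if (length(unique(sizes)) != 1L)
    stop_invalid_argument("patch sizes differ between sets")
  p <- sizes[1]
  n_tot <- sum(vapply(sets, n_patches, 1L))
  out <- array(as.raw(0), dim = c(p, p, 3L, n_tot))
  at <- 0L
  for (s in sets) {
    n <- n_patches(s)
    if (n > 0) out[, , , (at + 1L):(at + n)] <- s$pixels
    at <- at + n
  }
  meta <- do.call(rbind, lapply(sets, `[[`, "meta"))
  rownames(meta) <- NULL
  patch_set(out, meta, p)
}

#' Assign patient labels to patches
#'
#' Every patch's label is set to its patient's label under the requested
#' schema ("All ROIs from the same patient share the patient's label").
#'
#' @param ps an `hf_patches` object.
#' @param patient_table an `hf_cohort` or a data frame with columns
#'   `patient_id`, `label_v1`, `label_v2`.
#' @param schema `"v1"` (clinical) or `"v2"` (pathology-revised).
#' @return the patch set with updated labels.
#' @export
assign_labels <- function(ps, patient_table, schema = c("v1", "v2")) {
  schema <- match.arg(schema)
  labs <- cohort_labels(patient_table, schema)
  missing <- setdiff(unique(ps$meta$patient_id), names(labs))
  if (length(missing) > 0)
    stop_missing_label(sprintf("no label for patient(s): %s",
                               paste(missing, collapse = ", ")))
  ps$meta$label <- unname(labs[ps$meta$patient_id])
  ps
}

# map schema label strings to a failing-class logical
label_to_binary <- function(labels) {
  known_pos <- c("failing", "abnormal_or_heart_failure")
  known_neg <- c("non_failing", "within_normal_limits")
  unknown <- setdiff(unique(labels), c(known_pos, known_neg))
  if (length(unknown) > 0)
    stop_invalid_data(sprintf("unknown label value(s): %s",
                              paste(unknown, collapse = ", ")))
  labels %in% known_pos
}

#' Sample labeled patches for a set of patients
#'
#' Convenience wrapper: samples `n_per_roi` patches from every ROI of the
#' requested patients, labels them under the active schema, and concatenates.
#'
#' @param cohort an `hf_cohort`.
#' @param patient_ids patients to include (default all).
#' @param n_per_roi patches per ROI (default 100).
#' @param patch_px patch side (default 64).
#' @param rng_seed integer seed.
#' @param schema label schema, `"v1"` or `"v2"`.
#' @return an `hf_patches` object.
#' @export
sample_cohort_patches <- function(cohort, patient_ids = NULL, n_per_roi = 100,
                                  patch_px = 64, rng_seed = 1L,
                                  schema = c("v1", "v2")) {
  schema <- match.arg(schema)
  if (is.null(patient_ids)) patient_ids <- cohort$patients$patient_id
  rois <- Filter(function(r) r$patient_id %in% patient_ids, cohort$rois)
  seeds <- derive_seeds(rng_seed, length(rois))
  sets <- lapply(seq_along(rois), function(i)
    sample_patches(rois[[i]], n = n_per_roi, patch_px = patch_px,
                   rng_seed = seeds[i]))
  assign_labels(bind_patches(sets), cohort, schema)
}
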