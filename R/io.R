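# Small on-disk interchange helpers: masks as single-channel PNG, manifests
# and feature tables as CSV, selection/consensus reports as JSON.

#' Read and write tissue masks as single-channel PNG
#'
#' Masks are stored as 0/255 grayscale PNG.
#'
#' @param mask an `hf_mask`.
#' @param path file path.
#' @return `write_mask` the path invisibly; `read_mask` an `hf_mask` (with
#'   provenance `"otsu+manual"`, since a file round-trip loses the original
#'   threshold context unless supplied).
#' @export
write_mask <- function(mask, path) {
  if (!inherits(mask, "hf_mask")) stop_invalid_argument("`mask` must be an hf_mask")
  png::writePNG(mask$mask * 1, path)
  invisible(path)
}

#' @rdname write_mask
#' @param threshold_used gray level recorded in the restored mask.
#' @export
read_mask <- function(path, threshold_used = NA_integer_) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  structure(list(mask = m > 0.5, threshold_used = threshold_used,
                 provenance = "otsu+manual"),
            class = "hf_mask")
}

#' Write an ROI manifest CSV
#'
#' One row per ROI: `slide_id`, `roi_id`, `row`, `col`, `side_px`, `seed`.
#'
#' @param rois list of `hf_roi`.
#' @param path file path.
#' @param slide_id slide identifier recorded for every ROI.
#' @param seed the sampling seed recorded for every ROI.
#' @return the path, invisibly.
#' @export
write_roi_manifest <- function(rois, path, slide_id = "slide", seed = NA_integer_) {
  man <- data.frame(
    slide_id = slide_id,
    roi_id = vapply(rois, `[[`, "", "roi_id"),
    row = vapply(rois, `[[`, 0L, "row"),
    col = vapply(rois, `[[`, 0L, "col"),
    side_px = vapply(rois, `[[`, 0L, "side_px"),
    seed = seed)
  utils::write.csv(man, path, row.names = FALSE)
  invisible(path)
}

#' Export patches as PNG tiles with a sidecar manifest
#'
#' @param ps an `hf_patches` set.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_patches <- function(ps, dir) {
  if (!inherits(ps, "hf_patches")) stop_invalid_argument("`ps` must be hf_patches")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(n_patches(ps))
  for (i in seq_len(n_patches(ps))) {
    paths[i] <- file.path(dir, sprintf("patch%05d.png", i))
    png::writePNG(patch_pixels(ps, i) / 255, paths[i])
  }
  man <- cbind(ps$meta, path = paths)
  manifest <- file.path(dir, "patches.csv")
  utils::write.csv(man, manifest, row.names = FALSE)
  invisible(manifest)
}

#' Write a feature matrix as CSV
#'
#' One row per ROI with named feature columns, prefixed by `roi_id` and
#' `patient_id`.
#'
#' @param features matrix from [extract_feature_matrix()].
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_features_csv <- function(features, path) {
  df <- data.frame(roi_id = rownames(features),
                   patient_id = attr(features, "patient_id"),
                   features, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a feature-selection report as JSON
#'
#' @param selection an `hf_selected_features`.
#' @param path file path.
#' @return the path, invisibly.
#' @export
write_selection_json <- function(selection, path) {
  jsonlite::write_json(
    list(k = selection$k, indices = selection$indices,
         feature_names = selection$feature_names, scores = selection$scores),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Export a consensus-clustering report
#'
#' Writes per-k consensus matrices as CSV, a selection report JSON (areas,
#' delta-areas, selected k, flagged patients when labels are given) and a
#' consensus heatmap PNG at the selected k, ordered by dendrogram.
#'
#' @param result an `hf_consensus`.
#' @param dir output directory.
#' @param labels optional named patient-label vector for flagging.
#' @return the report path, invisibly.
#' @export
write_consensus_report <- function(result, dir, labels = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (k in result$k_range)
    utils::write.csv(result$matrices[[as.character(k)]],
                     file.path(dir, sprintf("consensus_k%d.csv", k)),
                     row.names = FALSE)
  cc <- consensus_cdf(result)
  sel <- select_k(result)
  flagged <- if (!is.null(labels) && !is.null(result$item_patients))
    flag_discordant_patients(result, labels, k = sel) else character(0)
  report <- file.path(dir, "selection.json")
  jsonlite::write_json(
    list(k_range = result$k_range, area = as.list(cc$area),
         delta_area = as.list(cc$delta_area), selected_k = sel,
         flagged_patients = flagged),
    report, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  M <- result$matrices[[as.character(sel)]]
  M[is.na(M)] <- 0
  ord <- stats::hclust(stats::as.dist(1 - M), method = "average")$order
  grDevices::png(file.path(dir, sprintf("consensus_k%d.png", sel)),
                 width = 600, height = 600)
  graphics::image(M[ord, ord], axes = FALSE, useRaster = TRUE,
                  main = sprintf("consensus matrix, k = %d", sel))
  grDevices::dev.off()
  invisible(report)
}
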