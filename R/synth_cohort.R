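# Seeded synthetic cohorts: patients, labels (two schemas), occult-pathology
# patients, and per-patient ROI rasters.

#' Cohort specification
#'
#' @param n_patients number of patients.
#' @param prop_failing proportion of patients with the failing label; the
#'   failing count is `round(n_patients * prop_failing)`.
#' @param occult_fraction proportion of non-failing-labeled patients rendered
#'   with severe (failing-like) tissue pathology.  Occult patients carry the
#'   label `non_failing` under schema v1 and `abnormal_or_heart_failure`
#'   under schema v2.
#' @param rois_per_patient regions of interest sampled per patient
#'   (default 11).
#' @param roi_side_px ROI side in pixels (default 1250 = 2.5 mm at 2 um/px).
#' @param mpp microns per pixel (default 2.0, i.e. 5x magnification).
#' @param effect_size class-separation preset: `"strong"`, `"moderate"` or
#'   `"weak"` (see [tissue_presets()]).
#' @param rng_seed integer master seed.
#' @return object of class `hf_cohort_spec`.
#' @export
cohort_spec <- function(n_patients, prop_failing = 0.5, occult_fraction = 0,
                        rois_per_patient = 11, roi_side_px = 1250, mpp = 2.0,
                        effect_size = c("strong", "moderate", "weak"),
                        rng_seed = 1L) {
  n_patients <- check_count(n_patients, "n_patients")
  check_proportion(prop_failing, "prop_failing")
  check_proportion(occult_fraction, "occult_fraction")
  rois_per_patient <- check_count(rois_per_patient, "rois_per_patient")
  roi_side_px <- check_count(roi_side_px, "roi_side_px", min = 128L)
  if (!is.numeric(mpp) || mpp <= 0)
    stop_invalid_argument("`mpp` must be positive")
  effect_size <- match.arg(effect_size)
  structure(list(n_patients = n_patients, prop_failing = prop_failing,
                 occult_fraction = occult_fraction,
                 rois_per_patient = rois_per_patient,
                 roi_side_px = roi_side_px, mpp = mpp,
                 effect_size = effect_size, rng_seed = as.integer(rng_seed)),
            class = "hf_cohort_spec")
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Generate a synthetic cohort
#'
#' Renders `rois_per_patient` independent tissue images per patient.  Exactly
#' `round(n_patients * prop_failing)` patients receive the failing phenotype;
#' occult patients are drawn only from the non-failing-labeled pool and are
#' rendered with the intermediate severe-pathology preset.  Per-patient and
#' per-ROI parameter jitter emulates biological heterogeneity (between-ROI
#' fibrosis sd 0.05, between-patient sd 0.025 around the preset means).
#'
#' @param spec an [cohort_spec()] object.
#' @return object of class `hf_cohort`: a list with `patients` (data frame of
#'   `patient_id`, `label_v1`, `label_v2`, `occult`, `phenotype`), `rois`
#'   (list of `hf_roi`, in patient order), and `spec`.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "hf_cohort_spec"))
    stop_invalid_argument("`spec` must be created by cohort_spec()")
  n <- spec$n_patients
  n_fail <- round(n * spec$prop_failing)
  pre <- tissue_presets(spec$effect_size)
  seeds <- derive_seeds(spec$rng_seed, 3L)

  # labels in a seeded random patient order
  lab <- withr::with_seed(seeds[1], sample(c(rep("failing", n_fail),
                                             rep("non_failing", n - n_fail))))
  ids <- sprintf("P%03d", seq_len(n))
  nf_idx <- which(lab == "non_failing")
  n_occ <- round(length(nf_idx) * spec$occult_fraction)
  occ_idx <- if (n_occ > 0)
    withr::with_seed(seeds[2], sample(nf_idx, n_occ)) else integer(0)
  occult <- seq_len(n) %in% occ_idx
  phenotype <- ifelse(lab == "failing", "failing",
                      ifelse(occult, "occult", "non_failing"))
  label_v2 <- ifelse(lab == "failing" | occult,
                     "abnormal_or_heart_failure", "within_normal_limits")
  patients <- data.frame(patient_id = ids, label_v1 = lab,
                         label_v2 = label_v2, occult = occult,
                         phenotype = phenotype, stringsAsFactors = FALSE)

  roi_seeds <- derive_seeds(seeds[3], n * (spec$rois_per_patient + 1L))
  rois <- vector("list", n * spec$rois_per_patient)
  k <- 0L
  for (i in seq_len(n)) {
    mu <- pre[[phenotype[i]]]
    pat_seed <- roi_seeds[(i - 1L) * (spec$rois_per_patient + 1L) + 1L]
    jit <- withr::with_seed(pat_seed, stats::rnorm(1, 0, pre$patient_sd))
    for (j in seq_len(spec$rois_per_patient)) {
      rs <- roi_seeds[(i - 1L) * (spec$rois_per_patient + 1L) + 1L + j]
      roi_jit <- withr::with_seed(rs, stats::rnorm(3))
      par <- tissue_params(
        fibrosis_fraction = clamp(mu$fibrosis_fraction + jit +
                                    pre$roi_sd * roi_jit[1], 0, 0.95),
        nucleus_density = mu$nucleus_density,
        nucleus_scale = max(1, mu$nucleus_scale + 0.05 * roi_jit[2]),
        fiber_disruption = clamp(mu$fiber_disruption + 0.03 * roi_jit[3], 0, 1),
        rng_seed = rs)
      k <- k + 1L
      roi <- region_of_interest(
        generate_tissue_image(par, side_px = spec$roi_side_px, mpp = spec$mpp),
        patient_id = ids[i], roi_id = sprintf("%s_roi%02d", ids[i], j))
      rois[[k]] <- roi
    }
  }
  structure(list(patients = patients, rois = rois, spec = spec),
            class = "hf_cohort")
}

#' @export
print.hf_cohort <- function(x, ...) {
  cat(sprintf(
    "<hf_cohort> %d patients (%d failing / %d non-failing, %d occult), %d ROIs of %d px\n",
    nrow(x$patients), sum(x$patients$label_v1 == "failing"),
    sum(x$patients$label_v1 == "non_failing"), sum(x$patients$occult),
    length(x$rois), x$spec$roi_side_px))
  invisible(x)
}

#' Active-schema labels for a cohort
#'
#' @param cohort an `hf_cohort` (or its `patients` data frame).
#' @param schema `"v1"` (clinical history) or `"v2"` (pathology-revised).
#' @return named character vector of labels, names = patient ids.
#' @export
cohort_labels <- function(cohort, schema = c("v1", "v2")) {
  schema <- match.arg(schema)
  pt <- if (inherits(cohort, "hf_cohort")) cohort$patients else cohort
  labs <- if (schema == "v1") pt$label_v1 else pt$label_v2
  stats::setNames(labs, pt$patient_id)
}

# failing-class name under each schema (the positive class)
positive_label <- function(schema = c("v1", "v2")) {
  schema <- match.arg(schema)
  if (schema == "v1") "failing" else "abnormal_or_heart_failure"
}

#' Write a cohort to disk
#'
#' Writes one 8-bit RGB PNG per ROI plus a cohort manifest CSV with columns
#' `patient_id`, `label_v1`, `label_v2`, `roi_paths` (semicolon-separated),
#' `seed`.  Slide rasters, when supplied, are written as TIFF with the
#' microns-per-pixel recorded in the image description.
#'
#' @param cohort an `hf_cohort`.
#' @param dir output directory (created if missing).
#' @param slides optional named list of `hf_slide` objects keyed by patient id.
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir, slides = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  roi_dir <- file.path(dir, "rois")
  dir.create(roi_dir, showWarnings = FALSE)
  paths <- character(length(cohort$rois))
  for (i in seq_along(cohort$rois)) {
    roi <- cohort$rois[[i]]
    paths[i] <- file.path(roi_dir, paste0(roi$roi_id, ".png"))
    png::writePNG(roi$pixels / 255, paths[i])
  }
  by_pat <- split(paths, vapply(cohort$rois, `[[`, "", "patient_id"))
  man <- cohort$patients
  man$roi_paths <- vapply(by_pat[man$patient_id], paste, "", collapse = ";")
  man$seed <- cohort$spec$rng_seed
  if (!is.null(slides)) {
    sl_dir <- file.path(dir, "slides")
    dir.create(sl_dir, showWarnings = FALSE)
    for (pid in names(slides)) {
      s <- slides[[pid]]
      tiff::writeTIFF(s$pixels / 255, file.path(sl_dir, paste0(pid, ".tiff")),
                      description = sprintf("mpp=%g", s$mpp))
    }
  }
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(man, manifest, row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory containing `manifest.csv`.
#' @return an `hf_cohort` (with `spec = NULL`; ROI geometry is taken from the
#'   PNG files).
#' @export
read_cohort <- function(dir) {
  manifest <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest))
    stop_invalid_argument(sprintf("no manifest.csv under '%s'", dir))
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  rois <- list()
  for (i in seq_len(nrow(man))) {
    for (p in strsplit(man$roi_paths[i], ";", fixed = TRUE)[[1]]) {
      px <- as_raster8(png::readPNG(p) * 255)
      rois[[length(rois) + 1L]] <- region_of_interest(
        px, patient_id = man$patient_id[i],
        roi_id = sub("\\.png$", "", basename(p)))
    }
  }
  patients <- man[, intersect(c("patient_id", "label_v1", "label_v2",
                                "occult", "phenotype"), names(man))]
  structure(list(patients = patients, rois = rois, spec = NULL),
            class = "hf_cohort")
}

#' Gaussian mixture fixture for clustering stages
#'
#' Draws `n_items_per_component` rows per component from spherical
#' unit-variance Gaussians whose centers are mutually `separation` apart
#' (centers are placed on scaled coordinate axes, so every pairwise
#' center distance equals `separation`).
#'
#' @param n_components number of mixture components (>= 1).
#' @param n_items_per_component rows per component.
#' @param separation pairwise distance between component centers (>= 0).
#' @param n_features feature dimension (>= 2, and >= n_components).
#' @param rng_seed integer seed.
#' @return list with `features` (matrix) and `assignments` (integer vector of
#'   true component labels).
#' @export
generate_feature_clusters <- function(n_components, n_items_per_component,
                                      separation, n_features, rng_seed = 1L) {
  n_components <- check_count(n_components, "n_components")
  n_items_per_component <- check_count(n_items_per_component, "n_items_per_component")
  n_features <- check_count(n_features, "n_features", min = 2L)
  if (!is.numeric(separation) || separation < 0)
    stop_invalid_argument("`separation` must be non-negative")
  if (n_components > n_features)
    stop_invalid_argument("`n_features` must be >= `n_components` for equidistant centers")
  n <- n_components * n_items_per_component
  assignments <- rep(seq_len(n_components), each = n_items_per_component)
  features <- withr::with_seed(as.integer(rng_seed), {
    # centers sit on mutually orthogonal unit vectors drawn from a random
    # rotation, so the separation energy spreads over all coordinates (the
    # geometry then survives per-feature standardization downstream)
    centers <- matrix(0, n_components, n_features)
    if (n_components > 1) {
      basis <- qr.Q(qr(matrix(stats::rnorm(n_features * n_components),
                              n_features, n_components)))
      centers <- t(basis) * (separation / sqrt(2))
    }
    matrix(stats::rnorm(n * n_features), n, n_features) +
      centers[assignments, , drop = FALSE]
  })
  rownames(features) <- sprintf("item%03d", seq_len(n))
  list(features = features, assignments = assignments)
}
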