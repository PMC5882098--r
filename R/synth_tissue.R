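# Synthetic H&E-like myocardial tissue rendering.
#
# The generator emulates the two tissue phenotypes the classifier must
# separate: non-failing myocardium (dense, coherently oriented myocyte fibers
# in eosin pink, stroma confined to perivascular regions, small nuclei) and
# failing myocardium (expanded pale collagen-like stroma, disrupted fiber
# orientation, enlarged hyperchromatic "boxcar" nuclei).  The texture model is
# deliberately simple: an oriented sinusoidal fiber field, a smooth blob-noise
# field thresholded to the requested stroma fraction, and Poisson-scattered
# elliptical nuclei aligned with the local fiber direction.

#' Reference H&E palette used by the renderer
#'
#' Color anchors (8-bit RGB) for the rendered tissue compartments.  Exposed so
#' that independent pixel-count checks can classify rendered pixels by
#' nearest palette center.
#'
#' @return named list of length-3 RGB vectors: `stroma`, `myocyte_dark`,
#'   `myocyte_light`, `nucleus`, `background`.
#' @export
hf_palette <- function() {
  list(
    stroma        = c(240, 218, 228),  # pale collagen pink
    myocyte_dark  = c(180,  90, 120),  # deep eosin
    myocyte_light = c(225, 150, 170),  # light eosin
    nucleus       = c( 70,  45, 110),  # hematoxylin purple
    background    = c(248, 248, 248)   # slide glass
  )
}

#' Tissue rendering parameters
#'
#' @param fibrosis_fraction proportion in `[0, 1]` of tissue area rendered as
#'   pale collagen-like stroma (beyond the small perivascular baseline).
#' @param nucleus_density nuclei per square millimetre.
#' @param nucleus_scale multiplier (>= 1) applied to nucleus size; enlarged
#'   nuclei are also rendered darker (hyperchromatic).
#' @param fiber_disruption proportion in `[0, 1]` of fiber-orientation
#'   coherence lost.
#' @param rng_seed integer seed; rendering is a pure function of the fields.
#' @return an object of class `hf_tissue_params`.
#' @export
tissue_params <- function(fibrosis_fraction = 0.05, nucleus_density = 350,
                          nucleus_scale = 1, fiber_disruption = 0.1,
                          rng_seed = 1L) {
  check_proportion(fibrosis_fraction, "fibrosis_fraction")
  check_proportion(fiber_disruption, "fiber_disruption")
  if (!is.numeric(nucleus_density) || nucleus_density < 0)
    stop_invalid_argument("`nucleus_density` must be a non-negative number")
  if (!is.numeric(nucleus_scale) || nucleus_scale < 1)
    stop_invalid_argument("`nucleus_scale` must be >= 1")
  structure(
    list(fibrosis_fraction = fibrosis_fraction,
         nucleus_density = nucleus_density,
         nucleus_scale = nucleus_scale,
         fiber_disruption = fiber_disruption,
         rng_seed = as.integer(rng_seed)),
    class = "hf_tissue_params"
  )
}

#' Class presets at a given effect size
#'
#' Mean tissue parameters for the non-failing and failing phenotypes, plus the
#' intermediate severe-pathology ("occult") phenotype, at three
#' class-separation levels.  Individual patients and regions receive seeded
#' jitter around these means (see [generate_cohort()]).
#'
#' @param effect_size one of `"strong"`, `"moderate"`, `"weak"`.
#' @return named list with elements `non_failing`, `failing`, `occult`, each a
#'   list of mean parameter values, plus `roi_sd` / `patient_sd`, the
#'   between-region and between-patient standard deviations of the fibrosis
#'   fraction.
#' @export
tissue_presets <- function(effect_size = c("strong", "moderate", "weak")) {
  effect_size <- match.arg(effect_size)
  p <- switch(effect_size,
    strong = list(
      non_failing = list(fibrosis_fraction = 0.05, nucleus_density = 350,
                         nucleus_scale = 1.00, fiber_disruption = 0.10),
      failing     = list(fibrosis_fraction = 0.45, nucleus_density = 300,
                         nucleus_scale = 1.80, fiber_disruption = 0.70),
      occult      = list(fibrosis_fraction = 0.80, nucleus_density = 350,
                         nucleus_scale = 1.00, fiber_disruption = 0.15)),
    moderate = list(
      non_failing = list(fibrosis_fraction = 0.10, nucleus_density = 350,
                         nucleus_scale = 1.00, fiber_disruption = 0.15),
      failing     = list(fibrosis_fraction = 0.30, nucleus_density = 320,
                         nucleus_scale = 1.40, fiber_disruption = 0.45),
      occult      = list(fibrosis_fraction = 0.60, nucleus_density = 350,
                         nucleus_scale = 1.00, fiber_disruption = 0.15)),
    weak = list(
      non_failing = list(fibrosis_fraction = 0.12, nucleus_density = 350,
                         nucleus_scale = 1.00, fiber_disruption = 0.20),
      failing     = list(fibrosis_fraction = 0.20, nucleus_density = 340,
                         nucleus_scale = 1.15, fiber_disruption = 0.30),
      occult      = list(fibrosis_fraction = 0.40, nucleus_density = 350,
                         nucleus_scale = 1.00, fiber_disruption = 0.18))
  )
  p$roi_sd <- 0.05
  p$patient_sd <- 0.025
  p$effect_size <- effect_size
  p
}

# Smooth zero-mean unit-sd Gaussian random field of size h x w.
smooth_field <- function(h, w, sigma_px) {
  z <- matrix(stats::rnorm(h * w), h, w)
  # gblur builds a 2*ceil(3*sigma)+1 kernel that must fit inside the image
  sigma_px <- min(sigma_px, floor((min(h, w) - 3) / 8))
  if (sigma_px >= 1) z <- EBImage::gblur(z, sigma = sigma_px)
  s <- stats::sd(z)
  if (s > 0) z <- (z - mean(z)) / s
  z
}

# Core renderer (no argument checks, any size); coordinates are row-major.
render_tissue <- function(params, h, w, mpp) {
  pal <- hf_palette()
  area_mm2 <- (h * mpp / 1000) * (w * mpp / 1000)
  scale_px <- 2 / mpp  # feature sizes are defined in microns at 2 um/px

  # fiber orientation field: one dominant direction, progressively scrambled
  theta0 <- stats::runif(1, 0, pi)
  theta_noise <- smooth_field(h, w, 12 * scale_px)
  theta <- theta0 + params$fiber_disruption * (pi / 2) * theta_noise

  row_ix <- matrix(seq_len(h), h, w)
  col_ix <- matrix(seq_len(w), h, w, byrow = TRUE)
  lambda <- 10 * scale_px  # ~20 um fiber striation period
  phase <- (row_ix * cos(theta) + col_ix * sin(theta)) * (2 * pi / lambda)
  v <- 0.5 + 0.5 * sin(phase)

  # stroma: smooth blob field thresholded at the quantile that yields the
  # requested fraction, plus a small perivascular baseline
  blob <- smooth_field(h, w, 25 * scale_px)
  f <- params$fibrosis_fraction
  stroma <- if (f > 0) blob > stats::quantile(blob, 1 - f) else
    matrix(FALSE, h, w)

  # perivascular stroma: a few vessel disks (~2% of area)
  r_v <- 6 * scale_px
  n_v <- max(1L, round(0.02 * h * w / (pi * r_v^2)))
  vessel <- matrix(FALSE, h, w)
  for (i in seq_len(n_v)) {
    cy <- stats::runif(1, 1, h); cx <- stats::runif(1, 1, w)
    rr <- r_v * stats::runif(1, 0.7, 1.3)
    y0 <- max(1, floor(cy - rr)); y1 <- min(h, ceiling(cy + rr))
    x0 <- max(1, floor(cx - rr)); x1 <- min(w, ceiling(cx + rr))
    sub_r <- (y0:y1) - cy
    sub_c <- (x0:x1) - cx
    d2 <- outer(sub_r^2, sub_c^2, `+`)
    vessel[y0:y1, x0:x1] <- vessel[y0:y1, x0:x1] | (d2 <= rr^2)
  }
  stroma <- stroma | vessel

  # compose RGB: myocyte striations under stroma overlay
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    myo <- pal$myocyte_dark[ch] + (pal$myocyte_light[ch] - pal$myocyte_dark[ch]) * v
    st <- pal$stroma[ch] + 6 * blob
    plane <- myo
    plane[stroma] <- st[stroma]
    img[, , ch] <- plane
  }

  # nuclei: Poisson-scattered ellipses elongated along the local fiber axis
  n_nuc <- stats::rpois(1, params$nucleus_density * area_mm2)
  if (n_nuc > 0) {
    a0 <- 2.5 * scale_px * params$nucleus_scale
    b0 <- 1.3 * scale_px * params$nucleus_scale
    darken <- params$nucleus_scale^(-0.5)  # enlarged nuclei are darker
    nuc_col <- pal$nucleus * darken
    cy <- stats::runif(n_nuc, 1, h)
    cx <- stats::runif(n_nuc, 1, w)
    size_jit <- stats::runif(n_nuc, 0.8, 1.2)
    for (i in seq_len(n_nuc)) {
      a <- a0 * size_jit[i]; b <- b0 * size_jit[i]
      phi <- theta[max(1, min(h, round(cy[i]))), max(1, min(w, round(cx[i])))] +
        pi / 2  # ellipse long axis runs along the fiber
      r <- ceiling(a) + 1
      y0 <- max(1, floor(cy[i] - r)); y1 <- min(h, ceiling(cy[i] + r))
      x0 <- max(1, floor(cx[i] - r)); x1 <- min(w, ceiling(cx[i] + r))
      if (y1 < y0 || x1 < x0) next
      dy <- matrix((y0:y1) - cy[i], y1 - y0 + 1, x1 - x0 + 1)
      dx <- matrix((x0:x1) - cx[i], y1 - y0 + 1, x1 - x0 + 1, byrow = TRUE)
      u <- (dy * cos(phi) + dx * sin(phi)) / a
      s <- (-dy * sin(phi) + dx * cos(phi)) / b
      inside <- (u^2 + s^2) <= 1
      for (ch in 1:3) {
        plane <- img[y0:y1, x0:x1, ch]
        plane[inside] <- nuc_col[ch]
        img[y0:y1, x0:x1, ch] <- plane
      }
    }
  }

  img <- img + array(stats::rnorm(h * w * 3, sd = 3), dim = c(h, w, 3))
  as_raster8(img)
}

#' Render a synthetic tissue image
#'
#' Produces an 8-bit RGB raster of myocardial tissue whose stroma-pixel
#' fraction approximates `params$fibrosis_fraction` (within the +-0.05
#' rendering tolerance; overlap of nuclei and vessels makes exact fractions
#' ill-defined).  Rendering is deterministic given `params` (including its
#' `rng_seed`), `side_px` and `mpp`.
#'
#' @param params an [tissue_params()] object.
#' @param side_px image side in pixels (>= 128).
#' @param mpp microns per pixel (> 0); feature sizes scale with `mpp` so that
#'   fibers and nuclei keep their physical size.
#' @return integer array of dim `c(side_px, side_px, 3)`, values 0..255.
#' @export
generate_tissue_image <- function(params, side_px = 1250, mpp = 2.0) {
  if (!inherits(params, "hf_tissue_params"))
    stop_invalid_argument("`params` must be created by tissue_params()")
  if (!is.numeric(side_px) || length(side_px) != 1L || side_px <= 0)
    stop_invalid_argument("`side_px` must be a positive integer")
  if (!is.numeric(mpp) || length(mpp) != 1L || mpp <= 0)
    stop_invalid_argument("`mpp` must be a positive number")
  if (side_px < 128)
    stop_invalid_argument("`side_px` must be >= 128")
  side_px <- as.integer(side_px)
  withr::with_seed(params$rng_seed, render_tissue(params, side_px, side_px, mpp))
}

#' Render a synthetic slide with background
#'
#' Places one connected, wobbly-edged tissue region of linear extent
#' `tissue_extent_px` on a near-white canvas, so that background/tissue
#' segmentation (Otsu masking) can be exercised end to end.  The tissue region
#' area approximates `tissue_extent_px^2`.
#'
#' @param params an [tissue_params()] object used to texture the tissue.
#' @param canvas_px canvas side in pixels.
#' @param tissue_extent_px linear extent of the tissue region; must be smaller
#'   than `canvas_px`.
#' @param rng_seed integer seed for canvas composition.
#' @param mpp microns per pixel stored in the slide metadata.
#' @param slide_id identifier stored in the slide.
#' @return an `hf_slide` object (see [slide_image()]).
#' @export
generate_slide <- function(params, canvas_px = 1024, tissue_extent_px = 700,
                           rng_seed = 1L, mpp = 2.0, slide_id = "synthetic") {
  if (!inherits(params, "hf_tissue_params"))
    stop_invalid_argument("`params` must be created by tissue_params()")
  canvas_px <- check_count(canvas_px, "canvas_px", min = 16L)
  check_count(tissue_extent_px, "tissue_extent_px", min = 16L)
  if (tissue_extent_px >= canvas_px)
    stop_invalid_argument("`tissue_extent_px` must be smaller than `canvas_px`")
  pal <- hf_palette()
  pixels <- withr::with_seed(as.integer(rng_seed), {
    h <- w <- canvas_px
    canvas <- array(rep(pal$background, each = h * w), dim = c(h, w, 3)) +
      array(stats::rnorm(h * w * 3, sd = 2), dim = c(h, w, 3))
    # wobbly square tissue region centered with a small jitter
    half <- tissue_extent_px / 2
    margin <- half + 0.06 * tissue_extent_px + 2
    cy <- stats::runif(1, margin, h - margin)
    cx <- stats::runif(1, margin, w - margin)
    wob <- smooth_field(h, w, max(4, round(canvas_px / 24)))
    row_ix <- matrix(seq_len(h), h, w)
    col_ix <- matrix(seq_len(w), h, w, byrow = TRUE)
    cheb <- pmax(abs(row_ix - cy), abs(col_ix - cx))
    region <- (cheb + 0.05 * tissue_extent_px * wob) < half
    tex <- render_tissue(params, h, w, mpp)
    for (ch in 1:3) {
      plane <- canvas[, , ch]
      tp <- tex[, , ch]
      plane[region] <- tp[region]
      canvas[, , ch] <- plane
    }
    as_raster8(canvas)
  })
  slide_image(pixels, mpp = mpp, slide_id = slide_id)
}
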