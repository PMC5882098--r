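#' @useDynLib hfhisto, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- classed error conditions -----------------------------------------------
# All user-facing failures are signalled as classed conditions so callers (and
# the test suite) can discriminate between invalid arguments, degenerate
# inputs, capacity failures and so on without string matching.

hf_stop <- function(class, msg, ...) {
  extra <- list(...)
  cond <- structure(
    class = c(class, "hf_error", "error", "condition"),
    c(list(message = msg, call = sys.call(-1)), extra)
  )
  stop(cond)
}

stop_invalid_argument <- function(msg, ...) hf_stop("hf_invalid_argument", msg, ...)
stop_degenerate_input <- function(msg, ...) hf_stop("hf_degenerate_input", msg, ...)
stop_invalid_data     <- function(msg, ...) hf_stop("hf_invalid_data", msg, ...)
stop_missing_label    <- function(msg, ...) hf_stop("hf_missing_label", msg, ...)
stop_invalid_state    <- function(msg, ...) hf_stop("hf_invalid_state", msg, ...)
stop_capacity         <- function(msg, ...) hf_stop("hf_capacity_error", msg, ...)
stop_invalid_architecture <- function(msg, ...) hf_stop("hf_invalid_architecture", msg, ...)
stop_config_drift     <- function(msg, ...) hf_stop("hf_config_drift", msg, ...)

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop_invalid_argument(sprintf("`%s` must be a single proportion in [0, 1]", name))
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x))
    stop_invalid_argument(sprintf("`%s` must be a single integer >= %d", name, min))
  invisible(as.integer(x))
}

# ---- raster helpers ---------------------------------------------------------
# Images are stored as integer arrays with dim c(height, width, 3) and values
# in 0..255 (8-bit RGB).  Masks are logical matrices congruent with the image.

as_raster8 <- function(x) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  storage.mode(x) <- "integer"
  x
}

#' Convert an RGB raster to grayscale
#'
#' Applies the Rec. 601 luma weights (0.299 R + 0.587 G + 0.114 B), the
#' standard photometric conversion used ahead of Otsu thresholding.
#'
#' @param pixels integer array of dim `c(h, w, 3)` with values in 0..255.
#' @return numeric matrix of gray levels in `[0, 255]`.
#' @export
rgb_to_gray <- function(pixels) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop_invalid_argument("`pixels` must be an h x w x 3 RGB array")
  0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
}

# Simple distribution moments used by the feature bank; a zero-variance input
# yields 0 for the shape statistics rather than NaN (degenerate texture
# convention used throughout the feature bank).
moment_stats <- function(x) {
  m <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) {
    sk <- 0; ku <- 0
  } else {
    z <- (x - m) / s
    sk <- mean(z^3)
    ku <- mean(z^4) - 3
  }
  c(mean = m, sd = ifelse(is.finite(s), s, 0), skew = sk, kurtosis = ku)
}

# Derive a stream of independent sub-seeds from one master seed, so that every
# nested generator stays a pure function of the top-level seed while remaining
# below .Machine$integer.max.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}
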