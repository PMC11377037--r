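#' @name chromatic_analysis
#' @title Luminance/color contrast space, spectral contrast, variance split
#'
#' @description
#' Maps each neuron into the 2-D (green, UV) peak-amplitude space for the
#' receptive-field center and surround. Achromatic On and Off cells fall in
#' the upper-right / lower-left quadrants along the diagonal ("luminance
#' axis"); color-opponent cells (opposite polarity in green and UV) fall in
#' the off-diagonal quadrants ("color axis"). The population's variance is
#' partitioned between the two axes by PCA on the 2-column point cloud.
NULL

#' Extract signed ETA peak amplitudes relative to baseline
#'
#' The amplitude of each condition's (reconstructed, if available) kernel is
#' the extremum of the deviation from the baseline mean within the
#' post-baseline response window; positive values mark On preference,
#' negative Off. Ties are broken toward the earliest extremum. Flat kernels
#' yield amplitude 0.
#'
#' @param etaset an `eta_set` (after [kernel_quality()]; reconstructed
#'   kernels from [apply_sparse_pca()] are used when present).
#' @param baseline_s baseline duration in seconds.
#' @param use_recon use reconstructed kernels when available (default TRUE).
#' @return data.frame with one row per included neuron: neuron_id, field,
#'   green_c, uv_c, green_s, uv_s, plus quadrant labels `quadrant_c`,
#'   `quadrant_s` (luminance-on, luminance-off, color-greenOn-uvOff,
#'   color-greenOff-uvOn, or undefined when a coordinate is 0).
#' @export
peak_amplitudes <- function(etaset, baseline_s = 0.5, use_recon = TRUE) {
  stopifnot(inherits(etaset, "eta_set"))
  kern <- if (use_recon && !is.null(etaset$recon)) etaset$recon else etaset$eta
  keep <- which(if (!is.null(etaset$include)) etaset$include
                else !etaset$excluded_zero)
  base_idx <- baseline_bins(etaset, baseline_s)
  resp_idx <- setdiff(seq_len(dim(kern)[1]), base_idx)
  amp1 <- function(k) {
    dev <- k[resp_idx] - mean(k[base_idx])
    i <- which.max(abs(dev))  # which.max returns the earliest maximum
    dev[i]
  }
  out <- data.frame(
    neuron_id = etaset$neurons$neuron_id[keep],
    field = etaset$neurons$field[keep],
    green_c = vapply(keep, function(i) amp1(kern[, "GreenC", i]), numeric(1)),
    uv_c = vapply(keep, function(i) amp1(kern[, "UVC", i]), numeric(1)),
    green_s = vapply(keep, function(i) amp1(kern[, "GreenS", i]), numeric(1)),
    uv_s = vapply(keep, function(i) amp1(kern[, "UVS", i]), numeric(1)),
    stringsAsFactors = FALSE
  )
  out$quadrant_c <- quadrant_label(out$green_c, out$uv_c)
  out$quadrant_s <- quadrant_label(out$green_s, out$uv_s)
  out
}

quadrant_label <- function(green, uv) {
  s <- sign(green) * sign(uv)
  ifelse(s == 0, "undefined",
         ifelse(s > 0,
                ifelse(green > 0, "luminance-on", "luminance-off"),
                ifelse(green > 0, "color-greenOn-uvOff", "color-greenOff-uvOn")))
}

#' Spectral contrast
#'
#' Michelson contrast of green versus UV response amplitude magnitudes:
#' `SC = (r_green - r_uv) / (r_green + r_uv)`, ranging from +1 for a neuron
#' responding solely to green to -1 for one responding solely to UV.
#'
#' @param r_green,r_uv non-negative amplitude magnitudes (vectorized).
#' @return SC in [-1, 1]; both inputs zero is an error for scalars, NA with
#'   a warning for vector entries.
#' @export
spectral_contrast <- function(r_green, r_uv) {
  if (any(r_green < 0, na.rm = TRUE) || any(r_uv < 0, na.rm = TRUE)) {
    abort("spectral_contrast takes amplitude magnitudes (non-negative)")
  }
  tot <- r_green + r_uv
  if (length(tot) == 1 && !is.na(tot) && tot == 0) {
    abort("spectral contrast undefined: both amplitudes are zero")
  }
  sc <- (r_green - r_uv) / tot
  if (any(tot == 0, na.rm = TRUE)) {
    warning("zero total amplitude: spectral contrast set to NA")
    sc[tot == 0] <- NA_real_
  }
  sc
}

#' Partition contrast-space variance between luminance and color axes
#'
#' PCA (eigendecomposition of the mean-centered 2x2 covariance) on the
#' (green, UV) points of one RF compartment. The principal axis closer in
#' absolute cosine to the diagonal (1,1)/sqrt(2) is labeled "luminance",
#' the orthogonal one "color"; the fractions are the normalized
#' eigenvalues, and sum to 1 exactly.
#'
#' @param points matrix or data.frame with 2 columns (green, UV).
#' @return object of class `variance_split`: `fraction_luminance`,
#'   `fraction_color`, `axes` (2x2, columns luminance/color unit vectors),
#'   `eigenvalues`, `n`.
#' @export
variance_split <- function(points) {
  pts <- as.matrix(points)
  if (nrow(pts) < 2 || ncol(pts) != 2) {
    abort("variance_split needs >= 2 points with 2 columns")
  }
  cv <- stats::cov(pts)
  if (sum(diag(cv)) <= 0) abort("zero total variance: split undefined")
  ei <- eigen(cv, symmetric = TRUE)
  diag_dir <- c(1, 1) / sqrt(2)
  cosines <- abs(as.vector(t(ei$vectors) %*% diag_dir))
  lum_idx <- which.max(cosines)  # tie -> PC1 (which.max takes the first)
  col_idx <- setdiff(1:2, lum_idx)
  frac <- ei$values / sum(ei$values)
  structure(
    list(fraction_luminance = frac[lum_idx],
         fraction_color = frac[col_idx],
         axes = cbind(luminance = ei$vectors[, lum_idx],
                      color = ei$vectors[, col_idx]),
         eigenvalues = c(luminance = ei$values[lum_idx],
                         color = ei$values[col_idx]),
         n = nrow(pts)),
    class = "variance_split"
  )
}

#' @export
print.variance_split <- function(x, ...) {
  cat(sprintf("<variance_split> luminance %.1f%% / color %.1f%% (n=%d)\n",
              100 * x$fraction_luminance, 100 * x$fraction_color, x$n))
  invisible(x)
}
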