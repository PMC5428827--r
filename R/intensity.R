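#' Intensity-histogram features
#'
#' The 11 first-order statistics of the in-ROI intensity distribution:
#' mean, median, min, max, range, standard deviation, variance,
#' skewness, kurtosis, histogram energy and histogram entropy (bits).
#' Moments use the population convention (`m_k / m_2^(k/2)`; kurtosis
#' is not excess-corrected). For the histogram, unresampled variants
#' use 16 HU-wide bins over the ROI threshold window and resampled
#' variants use their native levels; a constant region has entropy 0
#' and energy 1. Skewness and kurtosis of a zero-variance region are
#' defined as 0.
#'
#' @param image Processed image (HU, or levels for resampled variants).
#' @param mask Logical (thresholded) ROI mask.
#' @param variant Variant id or `"preproc_variant"`; controls the
#'   histogram binning.
#' @return Named numeric vector of length 11.
#' @export
intensity_features <- function(image, mask, variant = "raw") {
  stopifnot(identical(dim(image), dim(mask)))
  v <- image[mask]
  if (length(v) == 0) stop_empty_roi()
  q <- quantize_levels(image, variant)
  lev <- q$levels[mask]
  p <- tabulate(lev, nbins = q$n_levels)
  p <- p / sum(p)
  p <- p[p > 0]
  m <- mean(v)
  m2 <- mean((v - m)^2)
  skew <- if (m2 > 0) mean((v - m)^3) / m2^1.5 else 0
  kurt <- if (m2 > 0) mean((v - m)^4) / m2^2 else 0
  c(ih_mean = m, ih_median = median(v), ih_min = min(v), ih_max = max(v),
    ih_range = max(v) - min(v),
    ih_sd = if (length(v) > 1) sd(v) else 0,
    ih_variance = if (length(v) > 1) var(v) else 0,
    ih_skewness = skew, ih_kurtosis = kurt,
    ih_energy = sum(p^2), ih_entropy = -sum(p * log2(p)))
}
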