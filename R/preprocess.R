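#' Restrict an ROI mask to a Hounsfield-unit window
#'
#' Removes voxels outside `[lo_hu, hi_hu]` (bounds inclusive) from the
#' mask, the standard step that excludes normal lung and bone from a
#' gross-tumor-volume contour before feature extraction. The image is
#' not modified: thresholding restricts the ROI, it does not clip
#' intensities.
#'
#' @param image 3D HU array.
#' @param mask Logical array aligned with `image`.
#' @param lo_hu,hi_hu Inclusive HU window (defaults -100 and 200).
#' @param context Optional string (e.g. patient/week) included in the
#'   error message if the thresholded ROI comes out empty.
#' @return Logical mask, a subset of `mask`.
#' @examples
#' fx <- generate_fixture("sphere_r10")
#' m <- threshold_roi(fx$image, fx$mask)
#' all(m == fx$mask)
#' @export
threshold_roi <- function(image, mask, lo_hu = -100, hi_hu = 200,
                          context = NULL) {
  check_image_mask(image, mask)
  out <- mask & image >= lo_hu & image <= hi_hu
  if (!any(out)) stop_empty_roi(context)
  out
}

#' Low-pass Butterworth smoothing of an axial image stack
#'
#' Applies the radial Butterworth transfer function
#' `H(f) = 1 / sqrt(1 + (f/f_c)^(2 * order))` in the 2D frequency
#' domain, slice by slice. The cutoff is expressed as a frequency index
#' on a 512-sample DFT axis (the axial reconstruction matrix), i.e.
#' `f_c = cutoff / 512` cycles per sample, so the default 125
#' corresponds to 125/256 of the Nyquist frequency. DC gain is exactly
#' 1, so the slice mean is preserved.
#'
#' Smoothing is per-slice (2D) because axial CT slices are typically
#' much thicker than the in-plane voxel size, making isotropic 3D
#' filtering ill-defined; it is applied to the full image before any
#' masking so boundary voxels see their true neighbors.
#'
#' @param image 3D HU array.
#' @param order Filter order (>= 1, default 2).
#' @param cutoff Cutoff frequency index on a 512-sample axis (default 125).
#' @return Smoothed array, same dimensions.
#' @export
butterworth_smooth <- function(image, order = 2, cutoff = 125) {
  if (!is.array(image) || length(dim(image)) != 3L)
    stop("`image` must be a 3D array", call. = FALSE)
  if (cutoff <= 0) stop("`cutoff` must be positive", call. = FALSE)
  if (order < 1) stop("`order` must be >= 1", call. = FALSE)
  d <- dim(image)
  fc <- cutoff / 512
  fax <- function(n) {
    k <- 0:(n - 1)
    ((k + floor(n / 2)) %% n - floor(n / 2)) / n
  }
  f <- sqrt(outer(fax(d[1])^2, fax(d[2])^2, `+`))
  H <- 1 / sqrt(1 + (f / fc)^(2 * order))
  out <- image
  for (z in seq_len(d[3])) {
    s <- image[, , z]
    out[, , z] <- Re(fft(fft(s) * H, inverse = TRUE)) / (d[1] * d[2])
  }
  out
}

#' Quantize HU values to a fixed bit depth
#'
#' Maps the 12-bit CT dynamic range `[-1024, 3071]` linearly onto
#' `2^bits` levels: `level = floor((HU + 1024) / bin_width)` with
#' `bin_width = 4096 / 2^bits`, clamped to `[0, 2^bits - 1]`. At the
#' default 8 bits the bin width is 16 HU, chosen so neighboring-voxel
#' level differences reflect density changes rather than image noise.
#'
#' @param image 3D HU array.
#' @param bits Bit depth in 1..16 (default 8).
#' @return Array of integer levels in `[0, 2^bits - 1]`.
#' @examples
#' resample_bit_depth(array(c(-1024, 0, 3071), c(3, 1, 1)))[, 1, 1]
#' @export
resample_bit_depth <- function(image, bits = 8) {
  if (bits < 1 || bits > 16) stop("`bits` must be in 1..16", call. = FALSE)
  bw <- 4096 / 2^bits
  lev <- floor((image + 1024) / bw)
  array(pmin(pmax(lev, 0), 2^bits - 1), dim(image))
}

#' Image preprocessing variants
#'
#' The four preprocessing variants under which every texture/intensity
#' feature is screened: `raw` (ROI thresholding only), `smooth`
#' (thresholding + Butterworth smoothing), `resample8` (thresholding +
#' 8-bit depth resample) and `smooth_resample8` (all three, smoothing
#' before resampling).
#'
#' @param id One of `"raw"`, `"smooth"`, `"resample8"`,
#'   `"smooth_resample8"`.
#' @param order,cutoff Butterworth parameters (see
#'   [butterworth_smooth()]).
#' @param bits Bit depth for the resampled variants.
#' @return An object of class `"preproc_variant"`.
#' @seealso [apply_variant()]
#' @export
preprocessing_variant <- function(id = variant_ids(), order = 2,
                                  cutoff = 125, bits = 8) {
  id <- match.arg(id)
  structure(list(id = id,
                 smooth = id %in% c("smooth", "smooth_resample8"),
                 resample = id %in% c("resample8", "smooth_resample8"),
                 order = order, cutoff = cutoff, bits = bits),
            class = "preproc_variant")
}

#' @rdname preprocessing_variant
#' @export
variant_ids <- function() c("raw", "smooth", "resample8", "smooth_resample8")

#' Apply a preprocessing variant to an image and ROI
#'
#' Step order is threshold -> smooth (if enabled) -> resample (if
#' enabled). The HU threshold is always evaluated on the raw image and
#' applied to the mask; smoothing operates on the full unmasked image.
#'
#' @param image 3D HU array.
#' @param mask Logical ROI mask.
#' @param variant A `"preproc_variant"` or a variant id string.
#' @param context Passed to [threshold_roi()] for error reporting.
#' @return List with `image` (processed array), `mask` (thresholded
#'   mask) and `variant` (the id).
#' @export
apply_variant <- function(image, mask, variant, context = NULL) {
  if (is.character(variant)) variant <- preprocessing_variant(variant)
  stopifnot(inherits(variant, "preproc_variant"))
  tmask <- threshold_roi(image, mask, context = context)
  img <- image
  if (variant$smooth)
    img <- butterworth_smooth(img, variant$order, variant$cutoff)
  if (variant$resample)
    img <- resample_bit_depth(img, variant$bits)
  list(image = img, mask = tmask, variant = variant$id)
}

#' Gray-level axis for texture matrices
#'
#' Converts a processed image to integer gray levels for the matrix
#' builders. Resampled variants use their native quantization levels
#' (256 levels at 8 bits). Unresampled variants are binned into 16
#' HU-wide bins spanning the ROI threshold window `[-100, 200]` (19
#' bins), mirroring the 8-bit bin width so level differences track
#' density changes; values outside the window (possible after
#' smoothing) are clamped into the edge bins.
#'
#' @param image Processed image (HU, or levels for resampled variants).
#' @param variant Variant id or `"preproc_variant"`.
#' @param lo_hu,hi_hu HU window used for binning unresampled variants.
#' @return List with `levels` (integer array, 1-based) and `n_levels`.
#' @export
quantize_levels <- function(image, variant, lo_hu = -100, hi_hu = 200) {
  if (is.character(variant)) variant <- preprocessing_variant(variant)
  if (variant$resample) {
    list(levels = array(as.integer(image + 1), dim(image)),
         n_levels = as.integer(2^variant$bits))
  } else {
    nb <- as.integer(ceiling((hi_hu - lo_hu) / 16))
    lev <- floor((image - lo_hu) / 16) + 1
    list(levels = array(as.integer(pmin(pmax(lev, 1), nb)), dim(image)),
         n_levels = nb)
  }
}
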