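#' Texture and intensity features of one scan under one variant
#'
#' Applies the preprocessing variant, quantizes gray levels and
#' computes the 49 non-shape registry features (11 intensity-histogram,
#' 22 co-occurrence, 5 NGTDM, 11 run-length).
#'
#' @param image 3D HU array.
#' @param mask Logical ROI mask (un-thresholded; the HU window is
#'   applied internally).
#' @param variant Variant id or `"preproc_variant"`.
#' @param context Optional string for error messages.
#' @return Named numeric vector of length 49.
#' @export
extract_texture_features <- function(image, mask, variant = "raw",
                                     context = NULL) {
  pv <- if (is.character(variant)) preprocessing_variant(variant) else variant
  ap <- apply_variant(image, mask, pv, context = context)
  q <- quantize_levels(ap$image, pv)
  c(intensity_features(ap$image, ap$mask, pv),
    glcm_features(build_glcm(q$levels, ap$mask, n_levels = q$n_levels)),
    ngtdm_features(build_ngtdm(q$levels, ap$mask, n_levels = q$n_levels)),
    rlm_features(build_rlm(q$levels, ap$mask, n_levels = q$n_levels)))
}

#' Extract longitudinal feature tables from an image series
#'
#' Runs feature extraction over every scan of a patient's image series.
#' In screening mode (`selected = NULL`) the 49 texture/intensity
#' features are computed under all four preprocessing variants and the
#' 16 shape features once per scan (212 values per scan). In selected
#' mode, `selected` is a data.frame with columns `feature` and
#' `variant` (the manifest produced by [select_variants()]) and only
#' those combinations are returned. Scans whose thresholded ROI is
#' empty yield rows with `NA` values flagged in `missing`, not an
#' error.
#'
#' @param series A list of scans, each a list with `image`, `mask`,
#'   `spacing`, `week` and `dose_gy` (as produced by
#'   [generate_image_series()]).
#' @param patient_id Identifier copied into the output.
#' @param selected Optional feature -> variant manifest.
#' @return A long data.frame with columns `patient_id`, `week`,
#'   `dose_gy`, `variant`, `feature`, `value`, `volume_cm3`, `missing`.
#' @export
extract_all <- function(series, patient_id = "p1", selected = NULL) {
  reg <- feature_registry()
  tex_names <- reg$name[reg$category != "shape"]
  shape_names <- reg$name[reg$category == "shape"]
  out <- list()
  for (scan in series) {
    sf <- shape_features(scan$mask, scan$spacing)
    vol <- sf[["shape_volume_cm3"]]
    shape_keep <- if (is.null(selected)) shape_names
      else intersect(shape_names, selected$feature)
    if (length(shape_keep))
      out[[length(out) + 1L]] <- data.frame(
        patient_id = patient_id, week = scan$week, dose_gy = scan$dose_gy,
        variant = "none", feature = shape_keep,
        value = unname(sf[shape_keep]), volume_cm3 = vol, missing = FALSE,
        stringsAsFactors = FALSE)
    for (vid in variant_ids()) {
      want <- if (is.null(selected)) tex_names
        else selected$feature[selected$variant == vid]
      want <- intersect(want, tex_names)
      if (!length(want)) next
      vals <- tryCatch(
        extract_texture_features(scan$image, scan$mask, vid,
                                 context = paste0(patient_id, " week ",
                                                  scan$week)),
        deltarad_empty_roi = function(e) NULL)
      miss <- is.null(vals)
      out[[length(out) + 1L]] <- data.frame(
        patient_id = patient_id, week = scan$week, dose_gy = scan$dose_gy,
        variant = vid, feature = want,
        value = if (miss) NA_real_ else unname(vals[want]),
        volume_cm3 = vol, missing = miss, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
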