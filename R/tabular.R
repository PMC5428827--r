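#' Feature-level simulation of a cohort's radiomics tables
#'
#' Generates pretreatment and longitudinal feature tables directly from
#' the cohort's latent variables, bypassing voxel-level image synthesis
#' and extraction. This is the scale at which model-recovery studies
#' run: the planted structure is identical to the image path (baseline
#' surface irregularity encoded in `shape_compactness2`, dose-response
#' slopes proportional to the latent response rate), but a replicate
#' cohort costs milliseconds instead of minutes.
#'
#' Pretreatment table: `shape_compactness2` (linear in the latent shape
#' score with small measurement noise), `volume_cm3`, and three pure
#' noise features. Longitudinal table (weeks 0..n): `ngtdm_strength`
#' declines with cumulative dose at a patient-specific rate
#' proportional to the latent response rate (the planted delta
#' family); `rlm_gln` declines at a patient-specific rate drawn
#' independently of outcome (dose-responsive but non-prognostic);
#' `glcm_energy` declines at a common patient-independent rate; and
#' `ih_mean` is static. All have per-patient random baselines and
#' weekly measurement noise.
#'
#' @param cohort A `"synthetic_cohort"`.
#' @return List with `pretx` (wide data.frame, one row per patient) and
#'   `longitudinal` (long data.frame: `patient_id`, `week`, `dose_gy`,
#'   `feature`, `value`).
#' @export
generate_feature_tables <- function(cohort) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  cfg <- cohort$config
  n <- nrow(cohort$clinical)
  ids <- cohort$clinical$patient_id
  resp <- cohort$latent$response_rate
  shape_z <- cohort$latent$shape_z
  with_seed(derive_seed(cfg$seed, 55L), {
    pretx <- data.frame(
      patient_id = ids,
      shape_compactness2 = 0.55 + 0.08 * shape_z + rnorm(n, 0, 0.01),
      volume_cm3 = cohort$clinical$roi_volume_cm3,
      noise_f1 = rnorm(n), noise_f2 = rnorm(n), noise_f3 = rnorm(n),
      stringsAsFactors = FALSE)
    slopes <- list(
      ngtdm_strength = -0.05 * resp + rnorm(n, 0, 0.005),
      rlm_gln = -0.05 * exp(-rnorm(n) / 2) + rnorm(n, 0, 0.005),
      glcm_energy = rep(-0.03, n),
      ih_mean = rep(0, n))
    longi <- do.call(rbind, lapply(names(slopes), function(f) {
      base <- rnorm(n, 10, 2)
      do.call(rbind, lapply(seq_len(n), function(i) {
        sc <- cohort$scans[cohort$scans$patient_id == ids[i], ]
        data.frame(patient_id = ids[i], week = sc$week,
                   dose_gy = sc$dose_gy, feature = f,
                   value = base[i] + slopes[[f]][i] * sc$dose_gy +
                     rnorm(nrow(sc), 0, 0.3),
                   stringsAsFactors = FALSE)
      }))
    }))
    list(pretx = pretx, longitudinal = longi)
  })
}
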