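#' Configuration for the synthetic longitudinal cohort generator
#'
#' Defines the study conditions emulated by the generator: weekly 4DCT
#' imaging during chemoradiation of stage III NSCLC, two CT scanner
#' models, dose-dependent tumor shrinkage and texture homogenization,
#' and proportional-hazards outcomes with planted covariate effects.
#'
#' Each patient receives a standard-normal latent risk score and a
#' standard-normal baseline shape score. Outcomes are drawn from an
#' exponential proportional-hazards model whose log-hazard is a linear
#' function of the planted covariates: overall survival (OS) loads on
#' the shape score (`beta_shape`), the latent risk (`beta_delta`) and
#' T stage (`beta_clinical`); distant metastases (DM) on shape and
#' T stage; local-regional recurrence (LR) on the latent risk only.
#' The latent risk drives the imaging response: the tumor of a
#' low-risk patient shrinks and homogenizes faster per delivered Gy
#' (response rate `exp(-risk / 2)`), so delta-radiomics slopes carry
#' the planted hazard signal.
#'
#' @param n_patients Number of patients (>= 2).
#' @param n_weeks Number of weekly intra-treatment scans (>= 2,
#'   default 7; a pretreatment scan at week 0 is always added).
#' @param dose_per_week Dose increment per weekly scan in Gy
#'   (default 10, capped at the prescription).
#' @param scanner_fraction Proportion of scans acquired on scanner A
#'   (default 37/81, the week-one split between the two models).
#' @param beta_shape Log-hazard per SD of the baseline shape score
#'   (default 0.8).
#' @param beta_delta Log-hazard per SD of the latent risk score
#'   (default 0.8).
#' @param beta_clinical Log-hazard for advanced T stage (default 0.5).
#' @param scanner_offset_hu Additive HU offset of scanner B
#'   (default 20).
#' @param censoring_rate Target proportion of independently censored
#'   patients (default 0.2).
#' @param grid_dim Image grid size per axis in voxels (default 64).
#' @param spacing Voxel spacing in mm (default `c(1, 1, 2.5)`,
#'   the 0.98 mm-class in-plane resolution with 2.5 mm slices).
#' @param seed RNG seed.
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_patients, n_weeks = 7, dose_per_week = 10,
                          scanner_fraction = 37 / 81,
                          beta_shape = 0.8, beta_delta = 0.8,
                          beta_clinical = 0.5, scanner_offset_hu = 20,
                          censoring_rate = 0.2, grid_dim = 64L,
                          spacing = c(1, 1, 2.5), seed = 1L) {
  if (n_patients < 2) stop("`n_patients` must be >= 2", call. = FALSE)
  if (n_weeks < 2) stop("`n_weeks` must be >= 2", call. = FALSE)
  if (scanner_fraction < 0 || scanner_fraction > 1 ||
      censoring_rate < 0 || censoring_rate > 1)
    stop("proportions must lie in [0, 1]", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 n_weeks = as.integer(n_weeks),
                 dose_per_week = dose_per_week,
                 scanner_fraction = scanner_fraction,
                 beta_shape = beta_shape, beta_delta = beta_delta,
                 beta_clinical = beta_clinical,
                 scanner_offset_hu = scanner_offset_hu,
                 censoring_rate = censoring_rate,
                 grid_dim = as.integer(grid_dim), spacing = spacing,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Marginal distributions of the clinical factors (counts out of 107
# analyzed patients). Factors are drawn independently, except the
# dichotomized dose which is tied to the sampled prescription.
clinical_marginals <- function() {
  list(sex_m = 62 / 107, age_ge65 = 62 / 107, t34 = 58 / 107,
       n23 = 83 / 107,
       stage = c(II = 12, IIIa = 44, IIIb = 49, IV = 2) / 107,
       histology_squamous = 46 / 107,
       smoking = c(current = 34, former = 64, never = 9) / 107,
       pack_years = c(`0-24` = 20, `25-49` = 37, `50-74` = 28,
                      `75+` = 22) / 107,
       kps_ge90 = 52 / 107, rx74 = 72 / 107)
}

#' Generate a synthetic patient cohort
#'
#' Draws clinical factors from the marginal frequencies of the modeled
#' NSCLC population, assigns latent risk and shape scores, scanner
#' labels and cumulative dose per weekly scan, and generates
#' event/censoring days for the three endpoints (OS, DM, LR) from
#' exponential proportional-hazards models with the planted effects in
#' the configuration (see [cohort_config()]). Baseline hazards are set
#' so that median OS is about 640 days past the landmark with lower
#' event rates for DM and LR, and censoring is independent.
#'
#' @param config A `"cohort_config"`.
#' @return An object of class `"synthetic_cohort"`: a list with
#'   `clinical` (one row per patient: factors, entry day, baseline ROI
#'   volume, protocol flag), `scans` (patient x week: scanner label,
#'   cumulative dose), `outcomes` (patient x endpoint: event day,
#'   indicator), `latent` (risk `r`, shape score `shape_z`, response
#'   rate) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  mg <- clinical_marginals()
  with_seed(config$seed, {
    rx74 <- rbinom(n, 1, mg$rx74) == 1
    clinical <- data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      sex_m = rbinom(n, 1, mg$sex_m),
      age_ge65 = rbinom(n, 1, mg$age_ge65),
      t34 = rbinom(n, 1, mg$t34),
      n23 = rbinom(n, 1, mg$n23),
      stage = sample(names(mg$stage), n, replace = TRUE, prob = mg$stage),
      stage_3b_plus = NA_integer_,
      histology_squamous = rbinom(n, 1, mg$histology_squamous),
      smoking = sample(names(mg$smoking), n, replace = TRUE,
                       prob = mg$smoking),
      smoking_current = NA_integer_,
      pack_years = sample(names(mg$pack_years), n, replace = TRUE,
                          prob = mg$pack_years),
      pack_years_ge50 = NA_integer_,
      kps_ge90 = rbinom(n, 1, mg$kps_ge90),
      prescription_gy = ifelse(rx74, 74, 66),
      dose_gt70 = as.integer(rx74),
      entry_day = sample(0:30, n, replace = TRUE),
      roi_volume_cm3 = rlnorm(n, log(30), 0.5),
      protocol = "4DCT",
      stringsAsFactors = FALSE)
    clinical$stage_3b_plus <- as.integer(clinical$stage %in% c("IIIb", "IV"))
    clinical$smoking_current <- as.integer(clinical$smoking == "current")
    clinical$pack_years_ge50 <-
      as.integer(clinical$pack_years %in% c("50-74", "75+"))
    r <- rnorm(n)
    shape_z <- rnorm(n)
    latent <- data.frame(patient_id = clinical$patient_id, risk = r,
                         shape_z = shape_z,
                         response_rate = exp(-r / 2))
    # per-scan metadata, week 0 = pretreatment
    scans <- do.call(rbind, lapply(seq_len(n), function(i) {
      wk <- 0:config$n_weeks
      data.frame(patient_id = clinical$patient_id[i], week = wk,
                 scanner = sample(c("A", "B"), length(wk), replace = TRUE,
                                  prob = c(config$scanner_fraction,
                                           1 - config$scanner_fraction)),
                 dose_gy = pmin(wk * config$dose_per_week,
                                clinical$prescription_gy[i]),
                 stringsAsFactors = FALSE)
    }))
    # proportional-hazards outcomes per endpoint; censoring is a single
    # shared follow-up process per patient, its rate set so that about
    # `censoring_rate` of OS outcomes are censored at baseline hazard
    landmark <- 90
    h0 <- c(OS = log(2) / 640, DM = log(2) / 1100, LR = log(2) / 2600)
    lp <- list(
      OS = config$beta_shape * shape_z + config$beta_delta * r +
        config$beta_clinical * clinical$t34,
      DM = config$beta_shape * shape_z + config$beta_clinical * clinical$t34,
      LR = config$beta_delta * r)
    cr <- config$censoring_rate
    t_cn <- if (cr > 0) rexp(n, h0[["OS"]] * cr / (1 - cr)) else
      rep(Inf, n)
    outcomes <- do.call(rbind, lapply(names(h0), function(ep) {
      haz <- h0[[ep]] * exp(lp[[ep]])
      t_ev <- rexp(n, haz)
      data.frame(patient_id = clinical$patient_id, endpoint = ep,
                 event_day = clinical$entry_day + landmark +
                   ceiling(pmin(t_ev, t_cn)),
                 event = as.integer(t_ev <= t_cn),
                 stringsAsFactors = FALSE)
    }))
    structure(list(clinical = clinical, scans = scans, outcomes = outcomes,
                   latent = latent, config = config),
              class = "synthetic_cohort")
  })
}

#' Apply the cohort exclusion rules
#'
#' Removes patients with (i) a small pretreatment ROI volume
#' (strictly below `min_volume_cm3`), (ii) a non-conforming imaging
#' protocol, or (iii) any endpoint event before the landmark day.
#' A patient is tallied once under the first matching rule, in the
#' fixed order volume, protocol, early event, so the per-reason counts
#' are reproducible.
#'
#' @param cohort A `"synthetic_cohort"`.
#' @param min_volume_cm3 Minimum ROI volume in cm^3 (default 5;
#'   volumes equal to the bound are retained).
#' @param landmark_days Landmark in days from trial entry (default 90).
#' @return A list with `cohort` (filtered, same class) and `tally`
#'   (named counts: `volume`, `protocol`, `early_event`, `retained`).
#' @export
apply_exclusions <- function(cohort, min_volume_cm3 = 5,
                             landmark_days = 90) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  cl <- cohort$clinical
  if (any(is.na(cl$roi_volume_cm3)))
    stop("missing pretreatment ROI volume", call. = FALSE)
  early <- vapply(cl$patient_id, function(p) {
    oc <- cohort$outcomes[cohort$outcomes$patient_id == p, ]
    entry <- cl$entry_day[cl$patient_id == p]
    any(oc$event == 1 & oc$event_day < entry + landmark_days)
  }, logical(1))
  reason <- rep(NA_character_, nrow(cl))
  reason[is.na(reason) & cl$roi_volume_cm3 < min_volume_cm3] <- "volume"
  reason[is.na(reason) & cl$protocol != "4DCT"] <- "protocol"
  reason[is.na(reason) & early] <- "early_event"
  keep <- is.na(reason)
  out <- cohort
  out$clinical <- cl[keep, , drop = FALSE]
  out$scans <- cohort$scans[cohort$scans$patient_id %in%
                              cl$patient_id[keep], , drop = FALSE]
  out$outcomes <- cohort$outcomes[cohort$outcomes$patient_id %in%
                                    cl$patient_id[keep], , drop = FALSE]
  out$latent <- cohort$latent[keep, , drop = FALSE]
  list(cohort = out,
       tally = c(volume = sum(reason == "volume", na.rm = TRUE),
                 protocol = sum(reason == "protocol", na.rm = TRUE),
                 early_event = sum(reason == "early_event", na.rm = TRUE),
                 retained = sum(keep)))
}
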