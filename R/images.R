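#' Extract one patient's record from a cohort
#'
#' @param cohort A `"synthetic_cohort"`.
#' @param patient_id Patient identifier.
#' @return A list with `clinical` (one-row data.frame), `scans`,
#'   `outcomes` and `latent` for that patient.
#' @export
patient_record <- function(cohort, patient_id) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  i <- match(patient_id, cohort$clinical$patient_id)
  if (is.na(i)) stop("unknown patient: ", patient_id, call. = FALSE)
  list(clinical = cohort$clinical[i, , drop = FALSE],
       scans = cohort$scans[cohort$scans$patient_id == patient_id, ,
                            drop = FALSE],
       outcomes = cohort$outcomes[cohort$outcomes$patient_id == patient_id, ,
                                  drop = FALSE],
       latent = cohort$latent[i, , drop = FALSE])
}

#' Generate a longitudinal synthetic image series for one patient
#'
#' Builds a textured, irregular ellipsoidal tumor in lung-like
#' background on the configured grid, then evolves it across the
#' patient's scans: the volume shrinks and the interior texture
#' homogenizes at rates proportional to cumulative dose times the
#' patient's latent response rate. Scans acquired on scanner B receive
#' the configured additive HU offset plus extra acquisition noise.
#'
#' The tumor boundary is an ellipsoid level set perturbed by a smooth
#' random field whose amplitude grows with the patient's baseline
#' shape score, so surface irregularity (and hence compactness2) is a
#' planted, recoverable baseline covariate. Weekly masks are nested by
#' construction: under a positive shrink rate the voxel count is
#' non-increasing across weeks. Interior HU values stay within
#' approximately -50..150.
#'
#' @param patient A patient record from [patient_record()] (the
#'   `scans` component supplies weeks, cumulative doses and scanner
#'   labels).
#' @param latent Latent response rate (non-negative; 0 freezes the
#'   tumor so weekly images differ only by acquisition noise).
#' @param config The `"cohort_config"` (grid, spacing, scanner offset).
#' @param seed RNG seed for this series.
#' @param shrink_rate Fractional volume loss at full prescription for a
#'   response rate of 1 (default 0.45).
#' @param texture_decay Fractional texture-amplitude loss at full
#'   prescription for a response rate of 1 (default 0.7).
#' @return A list of scans, each a list with `image`, `mask`,
#'   `spacing`, `week`, `dose_gy`, `scanner`; generator parameters are
#'   attached as attribute `"params"`.
#' @export
generate_image_series <- function(patient, latent, config, seed = 1L,
                                  shrink_rate = 0.45, texture_decay = 0.7) {
  stopifnot(inherits(config, "cohort_config"))
  if (nrow(patient$scans) < 2) stop("need at least 2 scans", call. = FALSE)
  d <- rep(config$grid_dim, 3)
  sp <- config$spacing
  v0_mm3 <- patient$clinical$roi_volume_cm3 * 1000
  r0 <- (3 * v0_mm3 / (4 * pi))^(1 / 3)
  if (v0_mm3 < prod(sp)) stop("tumor smaller than 1 voxel", call. = FALSE)
  shape_z <- patient$latent$shape_z
  rx <- patient$clinical$prescription_gy
  amp <- 0.05 + 0.12 * stats::plogis(shape_z)
  with_seed(seed, {
    # physical coordinates relative to grid center
    ax <- lapply(1:3, function(k) (seq_len(d[k]) - (d[k] + 1) / 2) * sp[k])
    dist2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
    rad <- sqrt(dist2)
    # fixed per-patient fields: boundary perturbation + interior texture
    pert <- gaussian_smooth_3d(array(rnorm(prod(d)), d), 4)
    pert <- pert / sd(pert)
    tex <- gaussian_smooth_3d(array(rnorm(prod(d)), d), 2)
    tex <- tex / sd(tex)
    bg <- -750 + 40 * gaussian_smooth_3d(array(rnorm(prod(d)), d), 1.5)
    reff <- rad * (1 + amp * pert)  # perturbed radial coordinate
    lapply(seq_len(nrow(patient$scans)), function(si) {
      scan <- patient$scans[si, ]
      frac <- scan$dose_gy / rx
      vol_scale <- exp(-shrink_rate * latent * frac)
      sigma_w <- 45 * exp(-texture_decay * latent * frac)
      mask <- reff <= r0 * vol_scale^(1 / 3)
      if (!any(mask)) stop("tumor smaller than 1 voxel", call. = FALSE)
      img <- bg
      img[mask] <- pmin(pmax(50 + sigma_w * tex[mask] +
                               rnorm(sum(mask), 0, 5), -50), 150)
      if (scan$scanner == "B")
        img <- img + config$scanner_offset_hu + rnorm(prod(d), 0, 8)
      list(image = img, mask = mask, spacing = sp, week = scan$week,
           dose_gy = scan$dose_gy, scanner = scan$scanner)
    }) -> series
    attr(series, "params") <- list(seed = seed, shrink_rate = shrink_rate,
                                   texture_decay = texture_decay,
                                   amp = amp, latent = latent, r0_mm = r0)
    series
  })
}

#' Read and write images as NIfTI
#'
#' Thin wrappers around \pkg{RNifti} that carry the voxel spacing.
#'
#' @param image 3D array.
#' @param spacing Voxel spacing in mm.
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `write_image_nifti` returns the path invisibly;
#'   `read_image_nifti` returns a list with `image` and `spacing`.
#' @export
write_image_nifti <- function(image, spacing, path) {
  img <- RNifti::asNifti(image)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_image_nifti
#' @export
read_image_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  list(image = array(as.numeric(img), dim(img)),
       spacing = RNifti::pixdim(img)[seq_len(length(dim(img)))])
}

#' Write a synthetic cohort to disk
#'
#' Writes the clinical table, per-scan metadata, outcomes and an echo
#' of the generator configuration as plain-text files; optionally the
#' image series as NIfTI volumes (one image + mask per scan).
#'
#' @param cohort A `"synthetic_cohort"`.
#' @param dir Output directory (created if needed).
#' @param images Logical; also synthesize and write NIfTI volumes.
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir, images = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
            row.names = FALSE)
  write.csv(cohort$scans, file.path(dir, "scans.csv"), row.names = FALSE)
  write.csv(cohort$outcomes, file.path(dir, "outcomes.csv"),
            row.names = FALSE)
  cfg <- cohort$config
  writeLines(paste0(names(cfg), " = ",
                    vapply(cfg, function(x) paste(x, collapse = ","),
                           character(1))),
             file.path(dir, "config.txt"))
  if (images) {
    for (pid in cohort$clinical$patient_id) {
      rec <- patient_record(cohort, pid)
      series <- generate_image_series(
        rec, rec$latent$response_rate, cohort$config,
        seed = derive_seed(cfg$seed, match(pid, cohort$clinical$patient_id)))
      for (scan in series) {
        stub <- file.path(dir, sprintf("%s_week%d", pid, scan$week))
        write_image_nifti(scan$image, scan$spacing,
                          paste0(stub, "_image.nii.gz"))
        write_image_nifti(array(as.numeric(scan$mask), dim(scan$mask)),
                          scan$spacing, paste0(stub, "_mask.nii.gz"))
      }
    }
  }
  invisible(dir)
}
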