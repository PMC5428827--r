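#' The radiomics feature registry
#'
#' The fixed, ordered catalogue of the 65 base features computed by this
#' package: 16 shape, 11 intensity-histogram, 22 gray-level
#' co-occurrence (COM/GLCM), 5 neighborhood gray-tone difference
#' (NGTDM) and 11 run-length (RLM) features. Texture and intensity
#' features (49 in total) are screened under the four preprocessing
#' variants; shape features describe the contour and are computed once
#' per scan, giving 49 x 4 + 16 = 212 feature/preprocessing
#' combinations in screening mode.
#'
#' @return A data.frame with columns `name`, `category` (one of
#'   `shape`, `intensity`, `COM`, `NGTDM`, `RLM`) and `description`.
#' @examples
#' table(feature_registry()$category)
#' @export
feature_registry <- function() {
  shape <- c(
    shape_volume_cm3         = "ROI volume, voxel count x voxel volume (cm^3)",
    shape_surface_area_cm2   = "triangulated isosurface area (cm^2)",
    shape_compactness1       = "V / (sqrt(pi) * A^(3/2)), mesh-based",
    shape_compactness2       = "36*pi*V^2 / A^3, 1 for a sphere",
    shape_sphericity         = "pi^(1/3) * (6V)^(2/3) / A",
    shape_spherical_disproportion = "A / (4*pi*r_eq^2)",
    shape_surface_volume_ratio = "A / V (1/mm)",
    shape_max_diameter_mm    = "largest pairwise surface-voxel distance",
    shape_major_axis_mm      = "4 * sqrt(first PCA eigenvalue)",
    shape_minor_axis_mm      = "4 * sqrt(second PCA eigenvalue)",
    shape_least_axis_mm      = "4 * sqrt(third PCA eigenvalue)",
    shape_elongation         = "sqrt(lambda2 / lambda1)",
    shape_flatness           = "sqrt(lambda3 / lambda1)",
    shape_voxel_count        = "number of ROI voxels",
    shape_equiv_sphere_diameter_mm = "diameter of equal-volume sphere",
    shape_bbox_volume_fraction = "ROI volume / bounding-box volume")
  intensity <- c(
    ih_mean = "mean HU", ih_median = "median HU", ih_min = "minimum HU",
    ih_max = "maximum HU", ih_range = "max - min",
    ih_sd = "standard deviation", ih_variance = "variance",
    ih_skewness = "third standardized moment",
    ih_kurtosis = "fourth standardized moment",
    ih_energy = "sum of squared histogram probabilities",
    ih_entropy = "Shannon entropy of histogram (bits)")
  com <- c(
    glcm_energy = "sum p^2", glcm_entropy = "-sum p log2 p",
    glcm_contrast = "sum (i-j)^2 p",
    glcm_correlation = "(sum ij p - mu_x mu_y) / (sd_x sd_y)",
    glcm_homogeneity = "sum p / (1 + |i-j|)",
    glcm_inverse_diff_moment = "sum p / (1 + (i-j)^2)",
    glcm_dissimilarity = "sum |i-j| p",
    glcm_autocorrelation = "sum ij p",
    glcm_cluster_shade = "sum (i+j-mu_x-mu_y)^3 p",
    glcm_cluster_prominence = "sum (i+j-mu_x-mu_y)^4 p",
    glcm_cluster_tendency = "sum (i+j-mu_x-mu_y)^2 p",
    glcm_max_probability = "max p",
    glcm_sum_average = "sum k p_{x+y}(k)",
    glcm_sum_entropy = "-sum p_{x+y} log2 p_{x+y}",
    glcm_sum_variance = "sum (k - sum_average)^2 p_{x+y}(k)",
    glcm_diff_entropy = "-sum p_{x-y} log2 p_{x-y}",
    glcm_diff_variance = "sum (k - mu_{x-y})^2 p_{x-y}(k)",
    glcm_imc1 = "(HXY - HXY1) / max(HX, HY)",
    glcm_imc2 = "sqrt(1 - exp(-2 (HXY2 - HXY)))",
    glcm_variance = "sum (i - mu_x)^2 p_x(i)",
    glcm_inverse_diff_normalized = "sum p / (1 + |i-j|/K)",
    glcm_inverse_diff_moment_normalized = "sum p / (1 + ((i-j)/K)^2)")
  ngtdm <- c(
    ngtdm_coarseness = "1 / (eps + sum p_i s_i)",
    ngtdm_contrast = "[sum p_i p_j (i-j)^2 / (Ng(Ng-1))] * [sum s_i / N]",
    ngtdm_busyness = "sum p_i s_i / (eps + sum |i p_i - j p_j|)",
    ngtdm_complexity = "sum |i-j| (p_i s_i + p_j s_j) / (N (p_i + p_j))",
    ngtdm_strength = "sum p_i p_j (i-j)^2 / (eps + sum s_i)")
  rlm <- c(
    rlm_sre = "short run emphasis", rlm_lre = "long run emphasis",
    rlm_gln = "gray-level non-uniformity",
    rlm_rln = "run-length non-uniformity", rlm_rp = "run percentage",
    rlm_lgre = "low gray-level run emphasis",
    rlm_hgre = "high gray-level run emphasis",
    rlm_srlge = "short run low gray-level emphasis",
    rlm_srhge = "short run high gray-level emphasis",
    rlm_lrlge = "long run low gray-level emphasis",
    rlm_lrhge = "long run high gray-level emphasis")
  data.frame(
    name = c(names(shape), names(intensity), names(com), names(ngtdm),
             names(rlm)),
    category = rep(c("shape", "intensity", "COM", "NGTDM", "RLM"),
                   c(length(shape), length(intensity), length(com),
                     length(ngtdm), length(rlm))),
    description = unname(c(shape, intensity, com, ngtdm, rlm)),
    stringsAsFactors = FALSE)
}

#' Write the feature registry to CSV
#'
#' @param path Output file path.
#' @return Invisibly, the registry data.frame.
#' @export
write_feature_registry <- function(path) {
  reg <- feature_registry()
  write.csv(reg, path, row.names = FALSE)
  invisible(reg)
}
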