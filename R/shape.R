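#' Isoperimetric shape ratios from a volume and surface area
#'
#' Closed-form shape descriptors as functions of a body's volume `V`
#' and surface area `A`: compactness1 `V / (sqrt(pi) A^(3/2))`,
#' compactness2 `36 pi V^2 / A^3` (1 for a perfect sphere, pi/6 for a
#' cube), sphericity `pi^(1/3) (6V)^(2/3) / A`, spherical
#' disproportion `A / (4 pi r_eq^2)` with `r_eq = (3V / 4pi)^(1/3)`,
#' and the surface-to-volume ratio.
#'
#' @param volume Volume (mm^3).
#' @param area Surface area (mm^2).
#' @return Named numeric vector of the five ratio features.
#' @examples
#' r <- 1
#' shape_ratio_features(4 / 3 * pi * r^3, 4 * pi * r^2)[["compactness2"]]
#' @export
shape_ratio_features <- function(volume, area) {
  r_eq <- (3 * volume / (4 * pi))^(1 / 3)
  c(compactness1 = volume / (sqrt(pi) * area^1.5),
    compactness2 = 36 * pi * volume^2 / area^3,
    sphericity = pi^(1 / 3) * (6 * volume)^(2 / 3) / area,
    spherical_disproportion = area / (4 * pi * r_eq^2),
    surface_volume_ratio = area / volume)
}

#' Isosurface area and volume of a binary mask
#'
#' Triangulates the 0.5 level set of a Gaussian-smoothed copy of the
#' mask (marching tetrahedra with linear edge interpolation) and
#' returns the mesh surface area and the mesh-enclosed volume via the
#' divergence theorem. Pre-smoothing (default sigma 1 voxel) removes
#' the voxelization staircase so the area converges to the true
#' surface area; because area and volume come from the same closed
#' surface, the isoperimetric inequality bounds compactness2 at 1.
#' The mask is zero-padded so the surface is always closed.
#'
#' @param mask Logical 3D array.
#' @param spacing Voxel spacing in mm (length 3).
#' @param sigma Pre-smoothing standard deviation in voxels.
#' @return Named numeric vector `c(area = , volume = )` in mm^2 / mm^3.
#' @export
mesh_area_volume <- function(mask, spacing, sigma = 1) {
  stopifnot(length(dim(mask)) == 3L, length(spacing) == 3L)
  pad <- ceiling(3 * sigma) + 1L
  d <- dim(mask) + 2L * pad
  f <- array(0, d)
  f[pad + seq_len(dim(mask)[1]), pad + seq_len(dim(mask)[2]),
    pad + seq_len(dim(mask)[3])] <- as.numeric(mask)
  f <- gaussian_smooth_3d(f, sigma)
  av <- cpp_mesh_area_volume(as.numeric(f), as.integer(d),
                             as.numeric(spacing), 0.5)
  c(area = av[1], volume = av[2])
}

#' Shape features of a tumor ROI
#'
#' The 16 registry shape features of a binary mask with physical voxel
#' spacing. `shape_volume_cm3` and `shape_voxel_count` follow the
#' voxel-counting ROI-volume convention (used e.g. for the small-ROI
#' exclusion rule); the compactness/sphericity ratios and the surface
#' area are computed from the triangulated isosurface
#' ([mesh_area_volume()]) so that area and volume refer to the same
#' surface. Principal axis lengths are `4 * sqrt(eigenvalue)` of the
#' physical-coordinate covariance. The maximum 3D diameter is the
#' largest pairwise distance between boundary voxels (computed over
#' directional extreme points when the boundary is large). Shape is a
#' property of the contour: no HU thresholding or preprocessing is
#' applied.
#'
#' @param mask Logical 3D array (the clinical contour).
#' @param spacing Voxel spacing in mm (length 3).
#' @return Named numeric vector of length 16.
#' @export
shape_features <- function(mask, spacing) {
  stopifnot(length(dim(mask)) == 3L)
  n_vox <- sum(mask)
  if (n_vox == 0) stop("empty mask", call. = FALSE)
  voxvol <- prod(spacing)
  av <- mesh_area_volume(mask, spacing)
  ratios <- shape_ratio_features(av[["volume"]], av[["area"]])
  idx <- which(mask, arr.ind = TRUE)
  xyz <- sweep(idx, 2, spacing, `*`)
  # principal axes
  if (n_vox > 1) {
    ev <- eigen(stats::cov(xyz), symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
  } else ev <- c(0, 0, 0)
  # bounding box in physical units (voxel extents)
  ext <- apply(idx, 2, function(k) diff(range(k)) + 1) * spacing
  boundary <- mask & !erode_mask(mask)
  bidx <- which(boundary, arr.ind = TRUE)
  bxyz <- sweep(bidx, 2, spacing, `*`)
  max_diam <- max_pairwise_distance(bxyz)
  c(shape_volume_cm3 = n_vox * voxvol / 1000,
    shape_surface_area_cm2 = av[["area"]] / 100,
    shape_compactness1 = ratios[["compactness1"]],
    shape_compactness2 = ratios[["compactness2"]],
    shape_sphericity = ratios[["sphericity"]],
    shape_spherical_disproportion = ratios[["spherical_disproportion"]],
    shape_surface_volume_ratio = ratios[["surface_volume_ratio"]],
    shape_max_diameter_mm = max_diam,
    shape_major_axis_mm = 4 * sqrt(ev[1]),
    shape_minor_axis_mm = 4 * sqrt(ev[2]),
    shape_least_axis_mm = 4 * sqrt(ev[3]),
    shape_elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    shape_flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0,
    shape_voxel_count = n_vox,
    shape_equiv_sphere_diameter_mm = 2 * (3 * n_vox * voxvol / (4 * pi))^(1 / 3),
    shape_bbox_volume_fraction = n_vox * voxvol / prod(ext))
}

# 6-connected erosion; a voxel survives if all face neighbors are in
# the mask (grid border counts as outside).
erode_mask <- function(mask) {
  d <- dim(mask)
  shift_and <- function(m, ax, by) {
    out <- array(FALSE, d)
    src <- dst <- lapply(d, seq_len)
    if (by > 0) { dst[[ax]] <- (1 + by):d[ax]; src[[ax]] <- 1:(d[ax] - by) }
    else { dst[[ax]] <- 1:(d[ax] + by); src[[ax]] <- (1 - by):d[ax] }
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  e <- mask
  for (ax in 1:3) {
    e <- e & shift_and(mask, ax, 1L) & shift_and(mask, ax, -1L)
  }
  e
}

# Largest pairwise distance; exact for small point sets, otherwise
# evaluated on directional extreme points (a convex-hull vertex subset).
max_pairwise_distance <- function(xyz, exact_limit = 1500L) {
  n <- nrow(xyz)
  if (n == 1) return(0)
  if (n > exact_limit) {
    set <- integer(0)
    for (th in seq(0, pi, length.out = 12)) {
      for (ph in seq(0, 2 * pi, length.out = 24)) {
        u <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
        pr <- xyz %*% u
        set <- c(set, which.max(pr), which.min(pr))
      }
    }
    xyz <- xyz[unique(set), , drop = FALSE]
  }
  max(stats::dist(xyz))
}
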