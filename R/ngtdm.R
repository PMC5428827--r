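#' Build a neighborhood gray-tone difference matrix (NGTDM)
#'
#' For each gray level i, accumulates the occupancy `n_i`, probability
#' `p_i = n_i / N` and summed absolute difference
#' `s_i = sum |i - Abar|` over in-mask voxels of level i, where `Abar`
#' is the mean level of the voxel's 26-connected in-mask neighborhood.
#' Voxels with no in-mask neighbor are excluded; `N` counts the
#' retained voxels.
#'
#' @inheritParams build_glcm
#' @return A `"texture_matrix"` of kind `"NGTDM"` whose `table` holds
#'   one row per level with columns `level`, `n`, `p`, `s`.
#' @export
build_ngtdm <- function(levels, mask, n_levels) {
  stopifnot(identical(dim(levels), dim(mask)))
  m <- cpp_ngtdm(as.integer(levels), as.logical(mask),
                 as.integer(dim(levels)), as.integer(n_levels))
  N <- sum(m[, 1])
  if (N == 0)
    stop("degenerate NGTDM: no voxel has an in-mask neighbor", call. = FALSE)
  structure(list(kind = "NGTDM",
                 table = data.frame(level = seq_len(n_levels), n = m[, 1],
                                    p = m[, 1] / N, s = m[, 2]),
                 n_levels = as.integer(n_levels), n_voxels = N),
            class = "texture_matrix")
}

#' NGTDM texture features
#'
#' Coarseness, contrast, busyness, complexity and strength from the
#' neighborhood gray-tone difference matrix. `eps = 1e-6` guards the
#' denominators; degenerate conventions: a constant region has all
#' `s_i = 0`, so coarseness saturates at `1/eps`, and contrast,
#' busyness, complexity and strength are 0. Strength uses the
#' product-weight numerator `sum_i sum_j p_i p_j (i - j)^2`.
#'
#' @param tm A `"texture_matrix"` of kind `"NGTDM"`.
#' @param eps Denominator guard (default 1e-6).
#' @return Named numeric vector of length 5.
#' @export
ngtdm_features <- function(tm, eps = 1e-6) {
  stopifnot(inherits(tm, "texture_matrix"), tm$kind == "NGTDM")
  tb <- tm$table
  present <- tb$p > 0
  lv <- tb$level[present]
  p <- tb$p[present]
  s <- tb$s[present]
  N <- tm$n_voxels
  Ng <- length(lv)
  ps <- sum(p * s)
  coarseness <- 1 / (eps + ps)
  dif2 <- outer(lv, lv, function(a, b) (a - b)^2)
  pp <- outer(p, p)
  contrast <- if (Ng > 1)
    (sum(pp * dif2) / (Ng * (Ng - 1))) * (sum(s) / N) else 0
  busy_den <- sum(abs(outer(lv * p, lv * p, `-`)))
  busyness <- if (busy_den > 0) ps / busy_den else 0
  dif <- abs(outer(lv, lv, `-`))
  psum <- outer(p, p, `+`)
  pssum <- outer(p * s, p * s, `+`)
  complexity <- sum(dif * pssum / (N * psum))
  strength <- sum(pp * dif2) / (eps + sum(s))
  c(ngtdm_coarseness = coarseness, ngtdm_contrast = contrast,
    ngtdm_busyness = busyness, ngtdm_complexity = complexity,
    ngtdm_strength = strength)
}
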