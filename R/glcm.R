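#' The 13 unique 3D direction offsets at distance 1
#'
#' All 26-connected neighbor offsets modulo sign: each unordered
#' direction appears once, with the first nonzero component positive.
#'
#' @return A 13 x 3 integer matrix of (dx, dy, dz) offsets.
#' @export
offsets_3d <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  keep <- apply(g, 1, function(v) {
    nz <- v[v != 0]
    nz[1] > 0
  })
  out <- g[keep, , drop = FALSE]
  storage.mode(out) <- "integer"
  dimnames(out) <- NULL
  out
}

#' Build a gray-level co-occurrence matrix (GLCM)
#'
#' Counts symmetric co-occurrences of gray-level pairs over the given
#' spatial offsets; both voxels of a pair must lie inside the mask.
#' By default the 13 unique 3D directions at distance 1 are summed into
#' a single matrix (not averaged per direction), then normalized.
#'
#' @param levels Integer 3D array of gray levels in `1..n_levels`
#'   (see [quantize_levels()]).
#' @param mask Logical array aligned with `levels`.
#' @param offsets Integer matrix of (dx, dy, dz) offsets; default
#'   [offsets_3d()].
#' @param n_levels Number of gray levels.
#' @return An object of class `"texture_matrix"` with elements `kind`
#'   (`"GLCM"`), `matrix` (normalized, symmetric, sums to 1), `counts`,
#'   `n_levels` and `n_pairs`.
#' @export
build_glcm <- function(levels, mask, offsets = offsets_3d(), n_levels) {
  stopifnot(identical(dim(levels), dim(mask)))
  counts <- cpp_glcm_counts(as.integer(levels), as.logical(mask),
                            as.integer(dim(levels)),
                            matrix(as.integer(offsets), ncol = 3),
                            as.integer(n_levels))
  n_pairs <- sum(counts) / 2
  if (n_pairs < 2)
    stop("degenerate co-occurrence matrix: fewer than 2 in-mask neighbor pairs",
         call. = FALSE)
  structure(list(kind = "GLCM", matrix = counts / sum(counts),
                 counts = counts, n_levels = as.integer(n_levels),
                 n_pairs = n_pairs),
            class = "texture_matrix")
}

#' Co-occurrence (COM) texture features
#'
#' Computes the registry's 22 canonical co-occurrence features from a
#' normalized, symmetric GLCM. Logarithms are base 2; terms with zero
#' probability are dropped. For a single-level matrix, correlation and
#' the information measures are defined as 0.
#'
#' @param tm A `"texture_matrix"` of kind `"GLCM"` from [build_glcm()].
#' @return Named numeric vector of length 22.
#' @export
glcm_features <- function(tm) {
  stopifnot(inherits(tm, "texture_matrix"), tm$kind == "GLCM")
  P <- tm$matrix
  if (sum(P) <= 0) stop("zero-sum co-occurrence matrix", call. = FALSE)
  K <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  lv <- seq_len(K)
  mux <- sum(lv * px); muy <- sum(lv * py)
  sdx <- sqrt(sum((lv - mux)^2 * px)); sdy <- sqrt(sum((lv - muy)^2 * py))
  log2p <- function(p) ifelse(p > 0, log2(p), 0)
  # diagonal-sum and diagonal-difference distributions
  pxy_sum <- vapply(2:(2 * K), function(k) sum(P[i + j == k]), numeric(1))
  ks <- 2:(2 * K)
  pxy_dif <- vapply(0:(K - 1), function(k) sum(P[abs(i - j) == k]),
                    numeric(1))
  kd <- 0:(K - 1)
  sum_avg <- sum(ks * pxy_sum)
  mu_dif <- sum(kd * pxy_dif)
  HXY <- -sum(P * log2p(P))
  pxpy <- outer(px, py)
  HXY1 <- -sum(P * log2p(pxpy))
  HXY2 <- -sum(pxpy * log2p(pxpy))
  HX <- -sum(px * log2p(px)); HY <- -sum(py * log2p(py))
  denom_h <- max(HX, HY)
  imc1 <- if (denom_h > 0) (HXY - HXY1) / denom_h else 0
  imc2_arg <- 1 - exp(-2 * (HXY2 - HXY))
  imc2 <- sqrt(max(imc2_arg, 0))
  corr <- if (sdx > 0 && sdy > 0)
    (sum(i * j * P) - mux * muy) / (sdx * sdy) else 0
  c(glcm_energy = sum(P^2),
    glcm_entropy = HXY,
    glcm_contrast = sum((i - j)^2 * P),
    glcm_correlation = corr,
    glcm_homogeneity = sum(P / (1 + abs(i - j))),
    glcm_inverse_diff_moment = sum(P / (1 + (i - j)^2)),
    glcm_dissimilarity = sum(abs(i - j) * P),
    glcm_autocorrelation = sum(i * j * P),
    glcm_cluster_shade = sum((i + j - mux - muy)^3 * P),
    glcm_cluster_prominence = sum((i + j - mux - muy)^4 * P),
    glcm_cluster_tendency = sum((i + j - mux - muy)^2 * P),
    glcm_max_probability = max(P),
    glcm_sum_average = sum_avg,
    glcm_sum_entropy = -sum(pxy_sum * log2p(pxy_sum)),
    glcm_sum_variance = sum((ks - sum_avg)^2 * pxy_sum),
    glcm_diff_entropy = -sum(pxy_dif * log2p(pxy_dif)),
    glcm_diff_variance = sum((kd - mu_dif)^2 * pxy_dif),
    glcm_imc1 = imc1,
    glcm_imc2 = imc2,
    glcm_variance = sum((lv - mux)^2 * px),
    glcm_inverse_diff_normalized = sum(P / (1 + abs(i - j) / K)),
    glcm_inverse_diff_moment_normalized = sum(P / (1 + ((i - j) / K)^2)))
}
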