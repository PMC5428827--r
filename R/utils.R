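#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed`, then
#' restores the previous state, so generator functions are deterministic
#' without disturbing the caller's RNG stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a per-stage/per-patient seed from a master seed, kept inside
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  s <- (as.numeric(seed) + 104729 * as.numeric(offset)) %% 2147483646
  as.integer(s) + 1L
}

#' Separable Gaussian smoothing of a 3D array
#'
#' Convolves each axis with a discrete Gaussian kernel (radius 3 sigma,
#' in voxel units). Borders use renormalized (truncated) kernels so a
#' constant array is preserved exactly.
#'
#' @param arr Numeric 3D array.
#' @param sigma Standard deviation in voxels; scalar or length-3.
#' @return Smoothed array of the same dimensions.
#' @keywords internal
gaussian_smooth_3d <- function(arr, sigma) {
  stopifnot(length(dim(arr)) == 3)
  sigma <- rep_len(sigma, 3)
  d <- dim(arr)
  smooth_axis <- function(a, axis) {
    s <- sigma[axis]
    if (s <= 0) return(a)
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    n <- dim(a)[axis]
    # banded convolution matrix with truncated-kernel renormalization
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- (i - r):(i + r)
      ok <- j >= 1 & j <= n
      K[i, j[ok]] <- k[ok] / sum(k[ok])
    }
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- K %*% matrix(ap, dp[1], dp[2] * dp[3])
    dim(m) <- dp
    aperm(m, order(perm))
  }
  a <- smooth_axis(arr, 1L)
  a <- smooth_axis(a, 2L)
  smooth_axis(a, 3L)
}

# Common argument checks -------------------------------------------------

check_image_mask <- function(image, mask) {
  if (!is.array(image) || length(dim(image)) != 3L)
    stop("`image` must be a 3D array", call. = FALSE)
  if (!identical(dim(image), dim(mask)))
    stop("`image` and `mask` grids are not aligned", call. = FALSE)
  if (!all(is.finite(image)))
    stop("`image` contains non-finite values", call. = FALSE)
  invisible(TRUE)
}

stop_empty_roi <- function(context = NULL) {
  msg <- "thresholded ROI is empty"
  if (!is.null(context)) msg <- paste0(msg, " (", context, ")")
  stop(errorCondition(msg, class = c("deltarad_empty_roi", "error")))
}
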