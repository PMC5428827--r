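#' Build a gray-level run-length matrix (RLM)
#'
#' Counts maximal runs of constant gray level traced along each of the
#' 13 unique 3D directions, broken at the mask boundary, and
#' accumulated over all directions into a single matrix `r(g, l)`.
#'
#' @inheritParams build_glcm
#' @param directions Integer matrix of run directions; default
#'   [offsets_3d()].
#' @return A `"texture_matrix"` of kind `"RLM"` with `counts`
#'   (levels x run length), `n_runs` and `n_traversed`
#'   (`sum r(g,l) * l`, the number of in-mask voxel traversals).
#' @export
build_rlm <- function(levels, mask, directions = offsets_3d(), n_levels) {
  stopifnot(identical(dim(levels), dim(mask)))
  counts <- cpp_rlm_counts(as.integer(levels), as.logical(mask),
                           as.integer(dim(levels)),
                           matrix(as.integer(directions), ncol = 3),
                           as.integer(n_levels))
  n_runs <- sum(counts)
  if (n_runs == 0) stop("degenerate RLM: no runs", call. = FALSE)
  lmax <- max(which(colSums(counts) > 0))
  counts <- counts[, seq_len(lmax), drop = FALSE]
  structure(list(kind = "RLM", counts = counts,
                 n_levels = as.integer(n_levels), n_runs = n_runs,
                 n_traversed = sum(t(counts) * seq_len(lmax))),
            class = "texture_matrix")
}

#' Run-length texture features
#'
#' The 11 classical run-length statistics: short/long run emphasis
#' (SRE, LRE), gray-level and run-length non-uniformity (GLN, RLN), run
#' percentage (RP, runs per traversed voxel) and the low/high
#' gray-level emphases (LGRE, HGRE, SRLGE, SRHGE, LRLGE, LRHGE).
#'
#' @param tm A `"texture_matrix"` of kind `"RLM"`.
#' @return Named numeric vector of length 11.
#' @export
rlm_features <- function(tm) {
  stopifnot(inherits(tm, "texture_matrix"), tm$kind == "RLM")
  r <- tm$counts
  Nr <- tm$n_runs
  g <- row(r); l <- col(r)
  c(rlm_sre = sum(r / l^2) / Nr,
    rlm_lre = sum(r * l^2) / Nr,
    rlm_gln = sum(rowSums(r)^2) / Nr,
    rlm_rln = sum(colSums(r)^2) / Nr,
    rlm_rp = Nr / tm$n_traversed,
    rlm_lgre = sum(r / g^2) / Nr,
    rlm_hgre = sum(r * g^2) / Nr,
    rlm_srlge = sum(r / (g^2 * l^2)) / Nr,
    rlm_srhge = sum(r * g^2 / l^2) / Nr,
    rlm_lrlge = sum(r * l^2 / g^2) / Nr,
    rlm_lrhge = sum(r * g^2 * l^2) / Nr)
}
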