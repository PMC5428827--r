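#' Deterministic fixture images for oracle testing
#'
#' Returns small, fully deterministic image/mask pairs used to validate
#' the texture-matrix builders and shape features against brute-force
#' enumeration and closed forms. The grids are stored as literal arrays
#' so they cannot drift.
#'
#' Available fixtures:
#' \describe{
#'   \item{`const8`}{8x8x8 grid, every voxel 100 HU, mask covers all.}
#'   \item{`checker2`}{4x4x4 three-dimensional checkerboard alternating
#'     50 and 100 HU by voxel parity.}
#'   \item{`haralick4x4`}{A fixed 4x4x1 grid with 4 gray levels (values
#'     0..3), the classic worked example for co-occurrence counting.}
#'   \item{`sphere_r10`}{Digital ball of radius 10 voxels on a 25^3
#'     isotropic grid (100 HU inside, -800 outside; mask is the ball).}
#'   \item{`cube_s10`}{10x10x10 solid cube centered in a 16^3 grid.}
#' }
#'
#' @param name Fixture name.
#' @return A list with elements `image` (3D HU array), `mask` (logical
#'   array, same dims) and `spacing` (mm, length 3).
#' @examples
#' fx <- generate_fixture("haralick4x4")
#' dim(fx$image)
#' @export
generate_fixture <- function(name) {
  registry <- list(
    const8 = function() {
      d <- c(8L, 8L, 8L)
      list(image = array(100, d), mask = array(TRUE, d),
           spacing = c(1, 1, 1))
    },
    checker2 = function() {
      d <- c(4L, 4L, 4L)
      g <- expand.grid(x = 1:4, y = 1:4, z = 1:4)
      v <- ifelse((g$x + g$y + g$z) %% 2 == 0, 100, 50)
      list(image = array(v, d), mask = array(TRUE, d), spacing = c(1, 1, 1))
    },
    haralick4x4 = function() {
      m <- matrix(c(0, 0, 1, 1,
                    0, 0, 1, 1,
                    0, 2, 2, 2,
                    2, 2, 3, 3), nrow = 4, byrow = TRUE)
      list(image = array(m, c(4L, 4L, 1L)), mask = array(TRUE, c(4L, 4L, 1L)),
           spacing = c(1, 1, 1))
    },
    sphere_r10 = function() {
      n <- 25L
      ctr <- 13
      ax <- seq_len(n) - ctr
      r2 <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
      mask <- array(r2 <= 10^2, c(n, n, n))
      list(image = array(ifelse(mask, 100, -800), c(n, n, n)), mask = mask,
           spacing = c(1, 1, 1))
    },
    cube_s10 = function() {
      n <- 16L
      mask <- array(FALSE, c(n, n, n))
      mask[4:13, 4:13, 4:13] <- TRUE
      list(image = array(ifelse(mask, 100, -800), c(n, n, n)), mask = mask,
           spacing = c(1, 1, 1))
    }
  )
  if (!name %in% names(registry))
    stop("unknown fixture name: ", name, call. = FALSE)
  registry[[name]]()
}
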