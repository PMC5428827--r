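# Independent brute-force oracles for the texture-matrix builders and
# the Cox fitting contract. These deliberately use naive enumeration
# (per-voxel R loops) so they share no code path with the package.

oracle_glcm_counts <- function(levels, mask, offsets, n_levels) {
  d <- dim(levels)
  counts <- matrix(0L, n_levels, n_levels)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    if (!mask[x, y, z]) next
    for (o in seq_len(nrow(offsets))) {
      x2 <- x + offsets[o, 1]; y2 <- y + offsets[o, 2]; z2 <- z + offsets[o, 3]
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3])
        next
      if (!mask[x2, y2, z2]) next
      a <- levels[x, y, z]; b <- levels[x2, y2, z2]
      counts[a, b] <- counts[a, b] + 1L
      counts[b, a] <- counts[b, a] + 1L
    }
  }
  counts
}

oracle_ngtdm <- function(levels, mask, n_levels) {
  d <- dim(levels)
  n_i <- numeric(n_levels); s_i <- numeric(n_levels)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    if (!mask[x, y, z]) next
    nb <- c()
    for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      x2 <- x + dx; y2 <- y + dy; z2 <- z + dz
      if (x2 < 1 || x2 > d[1] || y2 < 1 || y2 > d[2] || z2 < 1 || z2 > d[3])
        next
      if (mask[x2, y2, z2]) nb <- c(nb, levels[x2, y2, z2])
    }
    if (!length(nb)) next
    g <- levels[x, y, z]
    n_i[g] <- n_i[g] + 1
    s_i[g] <- s_i[g] + abs(g - mean(nb))
  }
  list(n = n_i, s = s_i)
}

oracle_rlm_counts <- function(levels, mask, directions, n_levels) {
  d <- dim(levels)
  maxlen <- sum(d)
  counts <- matrix(0L, n_levels, maxlen)
  inside <- function(p) all(p >= 1) && all(p <= d)
  for (o in seq_len(nrow(directions))) {
    dir <- directions[o, ]
    for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
      p <- c(x, y, z)
      if (!mask[x, y, z]) next
      prev <- p - dir
      if (inside(prev) && mask[prev[1], prev[2], prev[3]] &&
          levels[prev[1], prev[2], prev[3]] == levels[x, y, z]) next
      len <- 1L
      nxt <- p + dir
      while (inside(nxt) && mask[nxt[1], nxt[2], nxt[3]] &&
             levels[nxt[1], nxt[2], nxt[3]] == levels[x, y, z]) {
        len <- len + 1L
        nxt <- nxt + dir
      }
      g <- levels[x, y, z]
      counts[g, len] <- counts[g, len] + 1L
    }
  }
  counts[, seq_len(max(which(colSums(counts) > 0))), drop = FALSE]
}

# Newton-Raphson maximizer of the Breslow partial likelihood, written
# from the score/information formulas.
oracle_cox_newton <- function(X, time, event, iter = 50, tol = 1e-10) {
  X <- as.matrix(X)
  beta <- rep(0, ncol(X))
  for (it in seq_len(iter)) {
    eta <- drop(X %*% beta)
    w <- exp(eta)
    score <- rep(0, ncol(X))
    info <- matrix(0, ncol(X), ncol(X))
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      sw <- sum(w[risk])
      xbar <- colSums(X[risk, , drop = FALSE] * w[risk]) / sw
      score <- score + X[i, ] - xbar
      xx <- t(X[risk, , drop = FALSE] * w[risk]) %*%
        X[risk, , drop = FALSE] / sw
      info <- info + xx - outer(xbar, xbar)
    }
    step <- solve(info, score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# random level/mask grids for property tests
random_level_grid <- function(dims, n_levels, p_mask = 0.8) {
  list(levels = array(sample.int(n_levels, prod(dims), replace = TRUE), dims),
       mask = array(runif(prod(dims)) < p_mask, dims))
}

small_cohort <- function(n = 40, seed = 11, ...) {
  generate_cohort(cohort_config(n, seed = seed, ...))
}
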