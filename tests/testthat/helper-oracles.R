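# Independent brute-force oracles for the similarity metrics, written
# deliberately in the most literal way possible (explicit loops and
# dense matrices) so they share no code path with the implementation.

oracle_dice <- function(mask1, mask2) {
  inter <- sum(mask1 & mask2)
  tot <- sum(mask1) + sum(mask2)
  if (tot == 0) return(NA_real_)
  2 * inter / tot
}

# internal contour by explicit neighbour enumeration
oracle_contour_indices <- function(mask) {
  d <- dim(mask)
  out <- matrix(0L, 0, 3)
  idx <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    boundary <- FALSE
    for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                     c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))) {
      ii <- i + off[1]; jj <- j + off[2]; kk <- k + off[3]
      if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] ||
          kk < 1 || kk > d[3] || !mask[ii, jj, kk]) {
        boundary <- TRUE
        break
      }
    }
    if (boundary) out <- rbind(out, c(i, j, k))
  }
  out
}

oracle_contour_world <- function(mask, grid) {
  idx <- oracle_contour_indices(mask)
  t(apply(idx, 1, function(v)
    (grid$affine %*% c(v - 1, 1))[1:3]))
}

# O(n^2) exhaustive contour distances
oracle_hd_nscd <- function(mask1, mask2, grid) {
  p1 <- oracle_contour_world(mask1, grid)
  p2 <- oracle_contour_world(mask2, grid)
  min12 <- apply(p1, 1, function(a)
    min(sqrt(colSums((t(p2) - a)^2))))
  min21 <- apply(p2, 1, function(a)
    min(sqrt(colSums((t(p1) - a)^2))))
  list(hd = max(max(min12), max(min21)),
       nscd = (sum(min12) + sum(min21)) / (nrow(p1) + nrow(p2)))
}

mask_world_points <- function(mask, grid) {
  idx <- which(mask, arr.ind = TRUE)
  t(apply(idx, 1, function(v) (grid$affine %*% c(v - 1, 1))[1:3]))
}

# dense-matrix covariance distance (normalized-product form)
oracle_covdist <- function(mask1, mask2, grid, alpha = 10) {
  c1 <- stats::cov(mask_world_points(mask1, grid))
  c2 <- stats::cov(mask_world_points(mask2, grid))
  tr <- sum(diag(c1 %*% c2))
  alpha * (1 - tr / (norm(c1, "F") * norm(c2, "F")))
}

random_blob_mask <- function(shape, n_seeds = 3, grow = 6) {
  # a connected-ish random mask: a few seed voxels dilated by random walks
  mask <- array(FALSE, dim = shape)
  for (s in seq_len(n_seeds)) {
    p <- sapply(shape, function(n) sample.int(n, 1))
    mask[p[1], p[2], p[3]] <- TRUE
    for (g in seq_len(grow)) {
      step <- sample(c(-1L, 0L, 1L), 3, replace = TRUE)
      p <- pmin(pmax(p + step, 1L), shape)
      mask[p[1], p[2], p[3]] <- TRUE
    }
  }
  mask
}

mask_region <- function(mask, grid = NULL) {
  vol <- label_volume(mask * 1L, grid)
  label_region(vol, 1L)
}

# literal multi-label STAPLE EM from the model equations: explicit loops,
# same conventions as the package (vote-frequency prior, 0.9-diagonal
# initialization, 1e-6 row regularization), no shared code
oracle_staple_em <- function(D, K, n_iter) {
  V <- nrow(D); N <- ncol(D)
  prior <- matrix(0, V, K)
  for (x in seq_len(V))
    for (i in seq_len(N))
      prior[x, D[x, i]] <- prior[x, D[x, i]] + 1 / N
  theta <- lapply(seq_len(N), function(i) {
    m <- matrix(0.1 / (K - 1), K, K); diag(m) <- 0.9; m
  })
  w <- matrix(0, V, K)
  for (iter in seq_len(n_iter)) {
    for (x in seq_len(V)) {
      for (t in seq_len(K)) {
        p <- prior[x, t]
        for (i in seq_len(N)) p <- p * theta[[i]][t, D[x, i]]
        w[x, t] <- p
      }
      w[x, ] <- w[x, ] / sum(w[x, ])
    }
    for (i in seq_len(N)) {
      th <- matrix(0, K, K)
      for (x in seq_len(V))
        for (t in seq_len(K))
          th[t, D[x, i]] <- th[t, D[x, i]] + w[x, t]
      th <- th + 1e-6
      theta[[i]] <- th / rowSums(th)
    }
  }
  list(w = w, theta = theta)
}

# Gaussian-windowed correlation at one voxel by explicit weighted sums
oracle_lncc_at <- function(I, J, center, sigma_vox) {
  d <- dim(I)
  w <- 0; si <- 0; sj <- 0; sii <- 0; sjj <- 0; sij <- 0
  r <- max(1L, ceiling(3 * sigma_vox))
  for (i in max(1, center[1] - r):min(d[1], center[1] + r))
    for (j in max(1, center[2] - r):min(d[2], center[2] + r))
      for (k in max(1, center[3] - r):min(d[3], center[3] + r)) {
        g <- exp(-sum((c(i, j, k) - center)^2) / (2 * sigma_vox^2))
        w <- w + g
        si <- si + g * I[i, j, k]; sj <- sj + g * J[i, j, k]
        sii <- sii + g * I[i, j, k]^2; sjj <- sjj + g * J[i, j, k]^2
        sij <- sij + g * I[i, j, k] * J[i, j, k]
      }
  mi <- si / w; mj <- sj / w
  cv <- sij / w - mi * mj
  vi <- sii / w - mi^2; vj <- sjj / w - mj^2
  cv / sqrt(vi * vj)
}

# small helper building a clean phantom population quickly
tiny_phantom <- function(seed, n_subjects = 2, ...) {
  cfg <- phantom_config(shape = c(24L, 28L, 20L), n_subjects = n_subjects,
                        n_paired = 3L, n_midline = 2L, seed = seed, ...)
  base <- make_base_phantom(cfg)
  list(cfg = cfg, base = base, pop = make_population(base, cfg))
}
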