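# Separable Gaussian filtering on 3-D arrays, implemented as banded
# matrix products along each axis (BLAS does the heavy lifting).
#
# Two boundary policies:
#   normalize = FALSE : zero padding (plain discrete convolution)
#   normalize = TRUE  : the filter computes a weighted local MEAN, i.e.
#                       the zero-padded convolution divided by the
#                       convolved indicator of the grid. This is the form
#                       needed for local (windowed) statistics like LNCC.

gauss_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

# n x n convolution matrix for a centered kernel (zero padding)
conv_matrix_1d <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (s in -r:r) {
    i <- seq_len(n)
    j <- i + s
    ok <- j >= 1 & j <= n
    K[cbind(i[ok], j[ok])] <- kernel[s + r + 1]
  }
  K
}

conv_axis <- function(arr, K, axis) {
  d <- dim(arr)
  if (axis == 1L) {
    array(K %*% matrix(arr, d[1], d[2] * d[3]), dim = d)
  } else if (axis == 2L) {
    perm <- c(2L, 1L, 3L)
    a <- aperm(arr, perm)
    a <- array(K %*% matrix(a, d[2], d[1] * d[3]), dim = d[perm])
    aperm(a, perm)
  } else {
    a <- matrix(arr, d[1] * d[2], d[3])
    array(a %*% t(K), dim = d)
  }
}

#' Separable Gaussian smoothing of a 3-D array
#'
#' @param arr numeric 3-D array.
#' @param sigma_vox Gaussian standard deviation in voxels, scalar or
#'   per-axis length 3; a sigma of 0 skips that axis.
#' @param normalize if TRUE, return the Gaussian-weighted local mean
#'   (boundary-renormalized); if FALSE, the zero-padded convolution.
#' @return smoothed array, same dimensions.
#' @keywords internal
smooth_gaussian <- function(arr, sigma_vox, normalize = FALSE) {
  d <- dim(arr)
  sigma_vox <- rep_len(sigma_vox, 3)
  out <- arr
  wt <- if (normalize) array(1, dim = d) else NULL
  for (ax in 1:3) {
    if (sigma_vox[ax] <= 0 || d[ax] == 1L) next
    K <- conv_matrix_1d(d[ax], gauss_kernel_1d(sigma_vox[ax]))
    out <- conv_axis(out, K, ax)
    if (normalize) wt <- conv_axis(wt, K, ax)
  }
  if (normalize) out / wt else out
}
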