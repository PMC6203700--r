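#' Image sampling grid
#'
#' An `image_grid` ties a 3-D voxel lattice to world (scanner) space through
#' a 4x4 affine in the NIfTI convention: 0-based voxel index -> world mm,
#' RAS+ orientation (+x right, +y anterior, +z superior). R arrays are
#' 1-based; the conversion helpers take care of the offset.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param spacing numeric length 3, mm per voxel along each axis. Ignored if
#'   `affine` is given (spacing is then read off the affine columns).
#' @param affine 4x4 voxel-index-to-world matrix; default is a diagonal
#'   affine built from `spacing` and `origin`.
#' @param origin world coordinate (mm) of voxel index (0,0,0); only used
#'   when `affine` is NULL.
#' @return an object of class `image_grid` with fields `shape`, `spacing`,
#'   `affine`, `orientation`.
#' @export
image_grid <- function(shape, spacing = c(1, 1, 1), affine = NULL,
                       origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  if (is.null(affine)) {
    stopifnot(length(spacing) == 3L, all(spacing > 0))
    affine <- diag(c(spacing, 1))
    affine[1:3, 4] <- origin
  }
  affine <- unclass(affine)[1:4, 1:4]
  attributes(affine) <- list(dim = c(4L, 4L))
  if (abs(det(affine)) < .Machine$double.eps * 64)
    stop("grid affine is singular")
  sp <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (!is.null(spacing) && !missing(spacing) && is.null(affine))
    stopifnot(max(abs(sp - spacing)) < 1e-6)
  structure(
    list(shape = shape, spacing = sp, affine = affine,
         orientation = orientation_codes(affine)),
    class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("image_grid %s, spacing %s mm, orientation %s\n",
              paste(x$shape, collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              x$orientation))
  invisible(x)
}

#' @export
format.image_grid <- function(x, ...)
  sprintf("%s @ %s mm", paste(x$shape, collapse = "x"),
          paste(signif(x$spacing, 4), collapse = "x"))

# anatomical orientation letters from the affine direction cosines
orientation_codes <- function(affine) {
  letters_pos <- c("R", "A", "S")
  letters_neg <- c("L", "P", "I")
  out <- character(3)
  for (j in 1:3) {
    col <- affine[1:3, j]
    ax <- which.max(abs(col))
    out[j] <- if (col[ax] >= 0) letters_pos[ax] else letters_neg[ax]
  }
  paste(out, collapse = "")
}

same_grid <- function(g1, g2, tol = 1e-6) {
  identical(g1$shape, g2$shape) &&
    max(abs(g1$affine - g2$affine)) < tol
}

stop_if_grid_mismatch <- function(g1, g2, what = "volumes") {
  if (!same_grid(g1, g2))
    stop(sprintf("%s are not on the same grid", what))
  invisible(TRUE)
}

#' Convert between voxel indices and world coordinates
#'
#' `voxel_to_world` maps 1-based R array indices to world mm;
#' `world_to_voxel` is the inverse. Both are vectorized over rows.
#'
#' @param grid an [image_grid].
#' @param idx n x 3 matrix of 1-based voxel indices (may be fractional).
#' @param xyz n x 3 matrix of world coordinates in mm.
#' @return n x 3 numeric matrix.
#' @export
voxel_to_world <- function(grid, idx) {
  idx <- rbind2mat(idx)
  if (nrow(idx) == 0L) return(idx)
  p <- cbind(idx - 1, 1) %*% t(grid$affine)
  p[, 1:3, drop = FALSE]
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(grid, xyz) {
  xyz <- rbind2mat(xyz)
  inv <- solve(grid$affine)
  p <- cbind(xyz, 1) %*% t(inv)
  p[, 1:3, drop = FALSE] + 1
}

rbind2mat <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3) else as.matrix(x)
}

# world coordinates (n x 3) of a set of linear voxel indices (1-based)
linear_index_world <- function(grid, lin) {
  idx <- arrayInd(lin, grid$shape)
  voxel_to_world(grid, idx)
}

# full lattice of 1-based voxel indices as an n x 3 matrix (column-major)
grid_index_matrix <- function(shape) {
  cbind(
    rep_len(seq_len(shape[1]), prod(shape)),
    rep(rep(seq_len(shape[2]), each = shape[1]), times = shape[3]),
    rep(seq_len(shape[3]), each = shape[1] * shape[2]))
}
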