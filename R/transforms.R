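#' Spatial transforms
#'
#' A transform is a map of world (mm) points. Three kinds are supported:
#' `affine` (4x4 homogeneous matrix, `rigid` being an affine whose linear
#' part is a rotation), `svf` (diffeomorphism parameterized by a
#' stationary velocity field, exponentiated by scaling and squaring), and
#' `composite` (transforms applied in sequence). Resampling uses the
#' "pull-back" convention: to warp a moving image onto a target grid, the
#' transform maps each target-space world point to the moving-space point
#' to sample.
#'
#' @param matrix 4x4 invertible homogeneous matrix.
#' @param kind `"affine"` or `"rigid"` (informational).
#' @return object of class `rba_transform`.
#' @export
affine_transform <- function(matrix, kind = c("affine", "rigid")) {
  kind <- match.arg(kind)
  matrix <- unclass(as.matrix(matrix))
  stopifnot(all(dim(matrix) == c(4L, 4L)))
  if (abs(det(matrix)) < .Machine$double.eps * 64)
    stop("affine transform matrix is singular")
  structure(list(kind = kind, matrix = matrix),
            class = c("affine_transform", "rba_transform"))
}

#' @rdname affine_transform
#' @param velocity array of dim `c(grid$shape, 3)`: stationary velocity in
#'   world mm per unit time, sampled on `grid`.
#' @param grid the [image_grid] carrying the field.
#' @export
svf_transform <- function(velocity, grid) {
  stopifnot(length(dim(velocity)) == 4L, dim(velocity)[4] == 3L,
            identical(as.integer(dim(velocity)[1:3]), grid$shape))
  if (!all(is.finite(velocity))) stop("velocity field contains non-finite values")
  structure(list(kind = "svf", velocity = velocity, grid = grid,
                 cache = new.env(parent = emptyenv())),
            class = c("svf_transform", "rba_transform"))
}

#' @rdname affine_transform
#' @param displacement array `c(shape, 3)` of world-mm displacements
#'   sampled on `grid`; the point map is `x + d(x)`. Used for dense
#'   fields read back from an external registration backend; unlike an
#'   SVF it carries no velocity and cannot be inverted.
#' @export
displacement_transform <- function(displacement, grid) {
  stopifnot(length(dim(displacement)) == 4L, dim(displacement)[4] == 3L,
            identical(as.integer(dim(displacement)[1:3]), grid$shape))
  if (!all(is.finite(displacement)))
    stop("displacement field contains non-finite values")
  structure(list(kind = "displacement", displacement = displacement,
                 grid = grid),
            class = c("displacement_transform", "rba_transform"))
}

#' @rdname affine_transform
#' @param transforms list of transforms; `transform_points` applies them
#'   in list order (first element first).
#' @export
composite_transform <- function(transforms) {
  stopifnot(all(vapply(transforms, inherits, TRUE, "rba_transform")))
  structure(list(kind = "composite", transforms = transforms),
            class = c("composite_transform", "rba_transform"))
}

#' @export
print.rba_transform <- function(x, ...) {
  cat("transform, kind:", x$kind, "\n")
  invisible(x)
}

#' Identity transform
#' @export
identity_transform <- function() affine_transform(diag(4), kind = "rigid")

#' Invert a transform
#'
#' Affine transforms invert exactly; an SVF diffeomorphism inverts by
#' negating the velocity; composites invert each member in reverse order.
#'
#' @param tf an `rba_transform`.
#' @return the inverse transform.
#' @export
invert_transform <- function(tf) {
  switch(tf$kind,
    affine = ,
    rigid = affine_transform(solve(tf$matrix), kind = tf$kind),
    svf = svf_transform(-tf$velocity, tf$grid),
    displacement = stop("dense displacement transforms are not invertible; ",
                        "request the inverse field from the backend"),
    composite = composite_transform(rev(lapply(tf$transforms,
                                               invert_transform))))
}

#' Exponential of a stationary velocity field
#'
#' Scaling and squaring: the velocity (in voxel units internally) is
#' divided by `2^steps`, then the small displacement is composed with
#' itself `steps` times. The zero field maps to the identity and a
#' constant field of `v` mm to the translation by `v` mm (exactly, up to
#' floating point).
#'
#' @param svf an `svf_transform`.
#' @param steps number of squarings; `NULL` picks the smallest number
#'   putting the scaled displacement below half a voxel.
#' @return array of dim `c(shape, 3)`: dense displacement field in world
#'   mm on the field's grid.
#' @export
exp_svf <- function(svf, steps = NULL) {
  stopifnot(inherits(svf, "svf_transform"))
  d <- svf$grid$shape
  A3 <- svf$grid$affine[1:3, 1:3]
  vm <- matrix(svf$velocity, prod(d), 3)
  vv <- vm %*% t(solve(A3))  # voxel-unit velocity
  u <- exp_disp_vox(vv, d, steps)
  array(u %*% t(A3), dim = c(d, 3))
}

# scaling-and-squaring on a voxel-unit velocity given as an nvox x 3
# matrix over a grid of dims d; returns the voxel-unit displacement
exp_disp_vox <- function(vv, d, steps = NULL) {
  maxdisp <- sqrt(max(rowSums(vv^2)))
  if (is.null(steps))
    steps <- max(1L, ceiling(log2(max(maxdisp, 1e-12) / 0.5)))
  steps <- max(1L, as.integer(steps))
  u <- vv / 2^steps
  pts <- grid_index_matrix(d)
  for (s in seq_len(steps)) {
    p <- pts + u
    u <- u + cbind(
      interp_trilinear(array(u[, 1], dim = d), p),
      interp_trilinear(array(u[, 2], dim = d), p),
      interp_trilinear(array(u[, 3], dim = d), p))
  }
  u
}

svf_displacement <- function(tf) {
  if (is.null(tf$cache$disp)) tf$cache$disp <- exp_svf(tf)
  tf$cache$disp
}

#' Apply a transform to world points
#'
#' @param tf an `rba_transform`.
#' @param pts n x 3 matrix of world coordinates (mm).
#' @return n x 3 matrix of mapped coordinates.
#' @export
transform_points <- function(tf, pts) {
  pts <- rbind2mat(pts)
  switch(tf$kind,
    affine = ,
    rigid = {
      p <- cbind(pts, 1) %*% t(tf$matrix)
      p[, 1:3, drop = FALSE]
    },
    svf = ,
    displacement = {
      disp <- if (tf$kind == "svf") svf_displacement(tf) else tf$displacement
      d <- tf$grid$shape
      vox <- world_to_voxel(tf$grid, pts)
      pts + cbind(
        interp_trilinear(array(disp[, , , 1], dim = d), vox),
        interp_trilinear(array(disp[, , , 2], dim = d), vox),
        interp_trilinear(array(disp[, , , 3], dim = d), vox))
    },
    composite = {
      for (t1 in tf$transforms) pts <- transform_points(t1, pts)
      pts
    })
}

#' Resample a volume through a transform
#'
#' For every voxel of `target_grid`, the transform maps its world
#' coordinate into the space of `vol`, where the value is interpolated:
#' trilinear for intensities, nearest-neighbour for labels (so no label
#' id is ever invented).
#'
#' @param vol a [label_volume] or [intensity_volume].
#' @param tf transform mapping target world points to source world points.
#' @param target_grid output [image_grid]; default: the input grid.
#' @param interp `"auto"` (nearest for labels, linear for intensities),
#'   `"linear"`, or `"nearest"`.
#' @return volume of the same class on `target_grid`.
#' @export
apply_transform <- function(vol, tf, target_grid = NULL,
                            interp = c("auto", "linear", "nearest")) {
  interp <- match.arg(interp)
  is_labels <- inherits(vol, "label_volume")
  if (interp == "auto") interp <- if (is_labels) "nearest" else "linear"
  if (is_labels && interp != "nearest")
    stop("label volumes must be resampled with nearest-neighbour interpolation")
  if (is.null(target_grid)) target_grid <- vol$grid
  pts <- voxel_to_world(target_grid, grid_index_matrix(target_grid$shape))
  src <- world_to_voxel(vol$grid, transform_points(tf, pts))
  arr <- if (is_labels) vol$labels else vol$values
  vals <- if (interp == "nearest") interp_nearest(arr, src)
          else interp_trilinear(arr, src)
  # points sampling outside the source grid become background / zero
  outside <- src[, 1] < 0.5 | src[, 1] > dim(arr)[1] + 0.5 |
             src[, 2] < 0.5 | src[, 2] > dim(arr)[2] + 0.5 |
             src[, 3] < 0.5 | src[, 3] > dim(arr)[3] + 0.5
  vals[outside] <- 0
  out <- array(vals, dim = target_grid$shape)
  if (is_labels) label_volume(out, target_grid)
  else intensity_volume(out, target_grid, vol$modality)
}
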