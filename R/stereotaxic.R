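#' Bicommissural landmarks
#'
#' The anterior and posterior commissure centers plus a mid-sagittal
#' plane estimate (point and unit normal), all in world mm.
#'
#' @param ac,pc length-3 world coordinates of the AC and PC centers.
#' @param plane_point point on the mid-sagittal plane (default: AC).
#' @param plane_normal plane normal; normalized on input.
#' @return object of class `landmarks`.
#' @export
landmarks <- function(ac, pc, plane_point = ac,
                      plane_normal = c(1, 0, 0)) {
  ac <- as.numeric(ac); pc <- as.numeric(pc)
  stopifnot(length(ac) == 3L, length(pc) == 3L)
  nrm <- sqrt(sum(plane_normal^2))
  if (nrm == 0) stop("plane normal must be nonzero")
  structure(list(ac = ac, pc = pc, plane_point = as.numeric(plane_point),
                 plane_normal = as.numeric(plane_normal) / nrm),
            class = "landmarks")
}

#' @export
print.landmarks <- function(x, ...) {
  cat(sprintf("landmarks: AC (%s) mm, PC (%s) mm\n",
              paste(signif(x$ac, 4), collapse = ", "),
              paste(signif(x$pc, 4), collapse = ", ")))
  invisible(x)
}

#' Transform landmarks through a point map
#' @param lm a [landmarks] object.
#' @param tf an `rba_transform` (must be affine/rigid so the plane normal
#'   transforms linearly).
#' @return transformed [landmarks].
#' @export
transform_landmarks <- function(lm, tf) {
  stopifnot(tf$kind %in% c("rigid", "affine"))
  R <- tf$matrix[1:3, 1:3]
  landmarks(ac = as.vector(transform_points(tf, lm$ac)),
            pc = as.vector(transform_points(tf, lm$pc)),
            plane_point = as.vector(transform_points(tf, lm$plane_point)),
            plane_normal = as.vector(solve(t(R)) %*% lm$plane_normal))
}

#' Stereotaxic reorientation from bicommissural landmarks
#'
#' Computes the rigid transform (rotation + translation, determinant +1)
#' that brings the head into the stereotaxic frame used for the neonatal
#' rabbit brain: the mid-sagittal plane becomes x = 0, the AC center
#' becomes the origin, and the AC-to-PC direction lies in the x = 0 plane
#' at 45 degrees below the horizontal (z = const) plane, with the PC
#' posterior-inferior to the AC. This replaces the rodent convention of a
#' horizontal bicommissural plane, which does not suit the rabbit brain
#' geometry.
#'
#' @param lm a [landmarks] object.
#' @param angle_deg angle between the bicommissural direction and the
#'   horizontal plane in the reoriented frame (default 45).
#' @param tol minimal AC-PC distance (mm).
#' @return a rigid `rba_transform` mapping input world points to
#'   stereotaxic world points.
#' @export
stereotaxic_transform <- function(lm, angle_deg = 45, tol = 1e-6) {
  d <- lm$pc - lm$ac
  if (sqrt(sum(d^2)) < tol)
    stop("AC and PC coincide (distance below tolerance)")
  n <- lm$plane_normal
  dp <- d - sum(d * n) * n
  ndp <- sqrt(sum(dp^2))
  if (ndp < tol)
    stop("AC-PC direction is orthogonal to the mid-sagittal plane")
  dp <- dp / ndp
  v <- cross3(n, dp)
  theta <- angle_deg * pi / 180
  ex <- c(1, 0, 0)
  u <- c(0, -cos(theta), -sin(theta))  # posterior-inferior
  w <- cross3(ex, u)
  R <- cbind(ex, u, w) %*% t(cbind(n, dp, v))
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- -R %*% lm$ac
  affine_transform(M, kind = "rigid")
}

cross3 <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

#' Angle of the bicommissural direction to the horizontal plane
#'
#' @param lm a [landmarks] object (typically after reorientation).
#' @return angle in degrees between the AC-PC direction and the
#'   z = const plane.
#' @export
bicommissural_angle <- function(lm) {
  d <- lm$pc - lm$ac
  asin(abs(d[3]) / sqrt(sum(d^2))) * 180 / pi
}

#' A seeded random rigid pose
#'
#' Draws Euler angles and a translation uniformly within the given
#' ranges, using the current RNG state.
#'
#' @param max_angle largest rotation per axis (radians).
#' @param max_shift largest translation per axis (mm).
#' @param center rotation center (world mm).
#' @return a rigid `rba_transform`.
#' @export
random_rigid_transform <- function(max_angle = pi / 4, max_shift = 10,
                                   center = c(0, 0, 0)) {
  p <- c(stats::runif(3, -max_shift, max_shift),
         stats::runif(3, -max_angle, max_angle))
  affine_transform(rigid_matrix(p, center), kind = "rigid")
}

reflect_points <- function(pts, plane_point, plane_normal) {
  n <- plane_normal / sqrt(sum(plane_normal^2))
  s <- (pts[, 1] - plane_point[1]) * n[1] +
       (pts[, 2] - plane_point[2]) * n[2] +
       (pts[, 3] - plane_point[3]) * n[3]
  pts - 2 * outer(s, n)
}

#' Symmetrize a binary mask about the mid-sagittal plane
#'
#' Alternates Gaussian smoothing with mirror averaging: each iteration
#' smooths the mask, averages it with its reflection about the plane,
#' and re-thresholds at 0.5. Used to turn a coarse manual brain/skull
#' delineation into a clean mirror-symmetric region of interest.
#'
#' @param mask binary [label_volume].
#' @param plane list with `point` and `normal` (world mm).
#' @param iterations number of smoothing/symmetrization rounds.
#' @param sigma Gaussian sigma in mm (0 disables smoothing).
#' @return binary [label_volume], mirror-symmetric to within a voxel
#'   layer.
#' @export
symmetrize_mask <- function(mask, plane, iterations = 3L, sigma = 0.5) {
  stopifnot(inherits(mask, "label_volume"), iterations >= 1L)
  grid <- mask$grid
  arr <- (mask$labels > 0) * 1
  if (sum(arr) == 0) return(label_volume(arr * 0L, grid))
  pts <- voxel_to_world(grid, grid_index_matrix(grid$shape))
  refl_vox <- world_to_voxel(grid, reflect_points(pts, plane$point,
                                                  plane$normal))
  sig_vox <- sigma / grid$spacing
  for (it in seq_len(iterations)) {
    sm <- if (sigma > 0) smooth_gaussian(arr, sig_vox, normalize = TRUE)
          else arr
    mirrored <- array(interp_trilinear(sm, refl_vox), dim = grid$shape)
    arr <- ((sm + mirrored) / 2 >= 0.5) * 1
  }
  label_volume(arr, grid)
}

#' Reflect a segmentation to the contralateral hemisphere
#'
#' Voxels are reflected about the mid-sagittal plane (nearest-neighbour
#' resampling) and label ids are passed through [side_swap_map()], so a
#' refined left-hemisphere delineation lands on the right side with the
#' right-side ids, and vice versa; median labels keep their id.
#'
#' @param seg a [label_volume].
#' @param tax the [taxonomy] supplying side/pair metadata.
#' @param plane list with `point` and `normal` (world mm).
#' @return reflected, relabelled [label_volume].
#' @export
flip_hemisphere_segmentation <- function(seg, tax, plane) {
  check_labels_known(seg, tax)
  grid <- seg$grid
  pts <- voxel_to_world(grid, grid_index_matrix(grid$shape))
  refl_vox <- world_to_voxel(grid, reflect_points(pts, plane$point,
                                                  plane$normal))
  vals <- interp_nearest(seg$labels, refl_vox)
  swap <- side_swap_map(tax)
  lut <- integer(max(tax$entries$id) + 1L)
  lut[1] <- 0L
  lut[as.integer(names(swap)) + 1L] <- as.integer(swap)
  label_volume(array(lut[vals + 1L], dim = grid$shape), grid)
}

#' Artifact exclusion mask by intensity percentile
#'
#' Flags the ROI voxels whose intensity does not exceed the given
#' intensity percentile of the ROI, removing the upper-tail outliers
#' (e.g. susceptibility artefacts) before spatial alignment. The
#' percentile uses the inclusive nearest-rank convention: the threshold
#' is the value at rank `floor(p*n/100) + 1` (capped at `n`) of the
#' sorted ROI intensities.
#'
#' @param img an [intensity_volume].
#' @param roi binary [label_volume] on the same grid.
#' @param percentile in (50, 100].
#' @return binary [label_volume]: ROI voxels kept for registration.
#' @export
percentile_artifact_mask <- function(img, roi, percentile) {
  stopifnot(inherits(img, "intensity_volume"),
            inherits(roi, "label_volume"))
  stop_if_grid_mismatch(img$grid, roi$grid)
  if (!(percentile > 50 && percentile <= 100))
    stop("percentile must be in (50, 100]")
  inroi <- roi$labels > 0
  n <- sum(inroi)
  if (n == 0L) stop("empty ROI")
  v <- sort(img$values[inroi])
  thr <- v[min(n, floor(percentile * n / 100) + 1L)]
  label_volume((inroi & img$values <= thr) * 1L, img$grid)
}
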