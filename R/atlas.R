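#' Unbiased group-wise template construction
#'
#' Iterates: register every subject's T1 channel to the current template
#' (diffeomorphic, stationary velocity fields), average the warped
#' intensities, then remove the group bias by resampling the average
#' through the mean of the subject deformations, so the template drifts
#' toward the population barycenter rather than any one subject. Stops
#' early with a warning if the template change grows between iterations.
#'
#' @param subjects a [multi_atlas] or list of [atlas_subject]s with T1
#'   channels on a common grid.
#' @param params [registration_params] for the per-subject registrations.
#' @param iterations number of template refinement iterations.
#' @return list with `template` ([intensity_volume]), `transforms` (one
#'   per subject, template space to subject space), `subject_ids`, and
#'   `mean_displacement_mm` (mean residual deformation magnitude).
#' @export
groupwise_template <- function(subjects, params = registration_params(),
                               iterations = 4L) {
  if (inherits(subjects, "multi_atlas")) subjects <- subjects$subjects
  stopifnot(length(subjects) >= 2L, iterations >= 1L)
  grid <- subjects[[1]]$grid
  t1s <- lapply(subjects, function(s) {
    stop_if_grid_mismatch(grid, s$grid, "subject grids")
    if (is.null(s$modalities$T1)) stop("subject without T1 channel")
    s$modalities$T1
  })
  template <- intensity_volume(
    Reduce(`+`, lapply(t1s, `[[`, "values")) / length(t1s), grid, "T1")
  pts <- voxel_to_world(grid, grid_index_matrix(grid$shape))
  last_change <- Inf
  transforms <- NULL
  for (it in seq_len(iterations)) {
    transforms <- lapply(t1s, function(v)
      register(template, v, params))
    warped <- lapply(seq_along(t1s), function(i)
      apply_transform(t1s[[i]], transforms[[i]], target_grid = grid))
    avg <- Reduce(`+`, lapply(warped, `[[`, "values")) / length(warped)
    # de-bias: mean forward displacement of the subject maps
    dbar <- Reduce(`+`, lapply(transforms, function(tf)
      transform_points(tf, pts) - pts)) / length(transforms)
    debias <- displacement_transform(array(dbar, dim = c(grid$shape, 3)),
                                     grid)
    new_template <- apply_transform(intensity_volume(avg, grid, "T1"),
                                    debias, target_grid = grid)
    change <- mean(abs(new_template$values - template$values))
    template <- new_template
    # re-express the subject maps in the de-biased template coordinates,
    # so their mean deformation is (to first order) zero
    transforms <- lapply(transforms, function(tf)
      composite_transform(list(debias, tf)))
    if (change > last_change * 1.5) {
      warning("group-wise template diverging (change grew); stopping at ",
              "iteration ", it)
      break
    }
    last_change <- change
  }
  mean_disp <- sqrt(rowSums((Reduce(`+`, lapply(transforms, function(tf)
    transform_points(tf, pts) - pts)) / length(transforms))^2))
  list(template = template, transforms = transforms,
       subject_ids = vapply(subjects, `[[`, "", "id"),
       mean_displacement_mm = mean(mean_disp))
}

#' Probabilistic atlas from propagated segmentations
#'
#' For every label, the probability map is the fraction of subjects
#' whose segmentation, propagated to the template grid with
#' nearest-neighbour resampling, carries that label at the voxel
#' (indicator averaging over hard labels). Together with the background
#' map the probabilities partition unity at every voxel exactly.
#'
#' @param atlas a [multi_atlas] of segmented subjects.
#' @param transforms one transform per subject (template space to
#'   subject space), e.g. from [groupwise_template()].
#' @param template_grid the [image_grid] of the template.
#' @return object of class `probabilistic_atlas`: `probabilities`
#'   (4-D array, last dimension indexed by `labels`), `labels` (0 =
#'   background first), `grid`, `subject_ids`.
#' @export
probabilistic_labels <- function(atlas, transforms, template_grid) {
  subjects <- atlas$subjects
  if (length(transforms) != length(subjects))
    stop("need exactly one transform per subject (",
         length(subjects), " subjects, ", length(transforms),
         " transforms)")
  props <- lapply(seq_along(subjects), function(i) {
    seg <- subjects[[i]]$segmentation
    if (is.null(seg)) stop("subject '", subjects[[i]]$id,
                           "' has no segmentation")
    apply_transform(seg, transforms[[i]], target_grid = template_grid)
  })
  labs <- sort(unique(unlist(lapply(props, function(p)
    unique(as.vector(p$labels))))))
  labs <- union(0L, labs)
  prob <- array(0, dim = c(template_grid$shape, length(labs)))
  for (p in props)
    for (j in seq_along(labs))
      prob[, , , j] <- prob[, , , j] + (p$labels == labs[j])
  prob <- prob / length(props)
  structure(list(probabilities = prob, labels = labs,
                 grid = template_grid,
                 subject_ids = vapply(subjects, `[[`, "", "id")),
            class = "probabilistic_atlas")
}

#' @export
print.probabilistic_atlas <- function(x, ...) {
  cat(sprintf("probabilistic_atlas: %d label map(s) + background from %d subjects\n",
              length(x$labels) - 1L, length(x$subject_ids)))
  invisible(x)
}

#' Write a probabilistic atlas as NIfTI
#'
#' Either a single 4-D NIfTI (last dimension = labels, background first)
#' or one 3-D NIfTI per label.
#'
#' @param pa a `probabilistic_atlas`.
#' @param path output file (4-D mode) or directory (per-label mode).
#' @param per_label write one file per label instead of a 4-D volume.
#' @export
write_probabilistic_atlas <- function(pa, path, per_label = FALSE) {
  if (!per_label) {
    img <- RNifti::asNifti(pa$probabilities)
    img <- RNifti::`sform<-`(img, structure(pa$grid$affine, code = 2L))
    RNifti::writeNifti(img, path, datatype = "float")
    return(invisible(path))
  }
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  for (j in seq_along(pa$labels)) {
    vol <- intensity_volume(pa$probabilities[, , , j], pa$grid)
    write_intensity_volume(
      vol, file.path(path, sprintf("prob_label%03d.nii.gz", pa$labels[j])))
  }
  invisible(path)
}
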