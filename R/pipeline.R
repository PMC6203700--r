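#' Atlas subject and multi-atlas containers
#'
#' An `atlas_subject` bundles one subject's intensity channels, its
#' segmentation, and its region-of-interest / artifact masks, all on one
#' grid. A `multi_atlas` is an ordered collection of subjects sharing a
#' taxonomy.
#'
#' @param id subject identifier (character).
#' @param modalities named list modality -> [intensity_volume] (a `T1`
#'   channel is expected by the pipeline).
#' @param segmentation [label_volume] or NULL for an unsegmented target.
#' @param roi_mask,artifact_mask optional binary [label_volume]s.
#' @param landmarks optional [landmarks].
#' @return object of class `atlas_subject`.
#' @export
atlas_subject <- function(id, modalities, segmentation = NULL,
                          roi_mask = NULL, artifact_mask = NULL,
                          landmarks = NULL) {
  stopifnot(length(modalities) >= 1L)
  grid <- modalities[[1]]$grid
  for (m in modalities) stop_if_grid_mismatch(grid, m$grid,
                                              "subject volumes")
  for (v in list(segmentation, roi_mask, artifact_mask))
    if (!is.null(v)) stop_if_grid_mismatch(grid, v$grid, "subject volumes")
  if (!is.null(segmentation) && !is.null(roi_mask) &&
      any(segmentation$labels != 0L & roi_mask$labels == 0L))
    stop("segmentation has nonzero labels outside the ROI mask")
  structure(list(id = as.character(id), grid = grid,
                 modalities = modalities, segmentation = segmentation,
                 roi_mask = roi_mask, artifact_mask = artifact_mask,
                 landmarks = landmarks, auto_layers = list(),
                 version = 0L),
            class = "atlas_subject")
}

#' @export
print.atlas_subject <- function(x, ...) {
  cat(sprintf("atlas_subject '%s': channels [%s]%s\n", x$id,
              paste(names(x$modalities), collapse = ", "),
              if (is.null(x$segmentation)) ", unsegmented" else ""))
  invisible(x)
}

#' @rdname atlas_subject
#' @param subjects list of `atlas_subject`s.
#' @param taxonomy shared [taxonomy]; all segmentations are validated
#'   against it.
#' @export
multi_atlas <- function(subjects, taxonomy) {
  ids <- vapply(subjects, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate subject ids")
  for (s in subjects)
    if (!is.null(s$segmentation))
      check_labels_known(s$segmentation, taxonomy)
  structure(list(subjects = subjects, taxonomy = taxonomy,
                 provenance = list()),
            class = "multi_atlas")
}

#' @export
print.multi_atlas <- function(x, ...) {
  cat(sprintf("multi_atlas: %d subject(s), taxonomy '%s' (%d regions)\n",
              length(x$subjects), x$taxonomy$name,
              nrow(x$taxonomy$entries)))
  invisible(x)
}

#' @export
length.multi_atlas <- function(x) length(x$subjects)

# the segmentation other subjects should propagate: the manual layer if
# present, otherwise the most recent automatic layer
effective_segmentation <- function(subject) {
  if (!is.null(subject$segmentation)) return(subject$segmentation)
  if (length(subject$auto_layers))
    return(subject$auto_layers[[length(subject$auto_layers)]])
  NULL
}

#' Pipeline configuration
#'
#' @param affine [registration_params] for the initial ROI/pose
#'   alignment stage (rigid by default).
#' @param nonrigid [registration_params] for the diffeomorphic stage.
#' @param fusion [fusion_params]; the default is multi-modal majority
#'   voting, the configuration that performed best for automatic
#'   segmentation of the neonatal rabbit multi-atlas.
#' @param artifact_percentile percentile in (50, 100] for the intensity
#'   outlier mask.
#' @param symmetrize_iterations,symmetrize_sigma mask symmetrization
#'   settings (sigma in mm).
#' @param seed integer seed controlling every stochastic element.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(affine = registration_params(mode = "rigid",
                                                         levels = 2L),
                            nonrigid = registration_params(),
                            fusion = fusion_params("MV",
                                                   modalities = c("T1", "FA")),
                            artifact_percentile = 98,
                            symmetrize_iterations = 3L,
                            symmetrize_sigma = 0.5, seed = 1L) {
  stopifnot(artifact_percentile > 50, artifact_percentile <= 100,
            symmetrize_iterations >= 1L)
  structure(list(affine = affine, nonrigid = nonrigid, fusion = fusion,
                 artifact_percentile = artifact_percentile,
                 symmetrize_iterations = as.integer(symmetrize_iterations),
                 symmetrize_sigma = symmetrize_sigma,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Automatic segmentation of a new subject
#'
#' For each atlas subject: registers its T1 channel to the target within
#' the ROI masks (rigid/affine initialization followed by diffeomorphic
#' refinement), propagates its segmentation with nearest-neighbour
#' resampling and its intensity channels with trilinear resampling onto
#' the target grid, then fuses the propagated stack (default:
#' multi-modal majority voting). If the target has no ROI mask, the
#' first atlas's mask is propagated to it through a rigid registration.
#'
#' @param target an [atlas_subject] (its segmentation, if any, is
#'   ignored).
#' @param atlas a [multi_atlas] with at least one segmented subject.
#' @param config a [pipeline_config].
#' @return object of class `segmentation_result`: `segmentation` (fused
#'   [label_volume]), `stack` (the [propagated_stack]), `provenance`
#'   (parameters, seed, per-atlas status and timings).
#' @export
segment_new_subject <- function(target, atlas, config = pipeline_config()) {
  if (is.null(target$modalities$T1))
    stop("target must carry a T1 channel")
  usable <- Filter(function(s) !is.null(effective_segmentation(s)),
                   atlas$subjects)
  if (length(usable) < 1L) stop("no usable (segmented) atlas subject")
  with_local_seed(config$seed, {
    target_roi <- target$roi_mask
    if (is.null(target_roi)) {
      donor <- usable[[1]]
      tf0 <- register(target$modalities$T1, donor$modalities$T1,
                      config$affine)
      target_roi <- apply_transform(donor$roi_mask, tf0,
                                    target_grid = target$grid)
    }
    reg_mask <- target_roi
    if (!is.null(target$artifact_mask))
      reg_mask <- label_volume(
        (target_roi$labels > 0 & target$artifact_mask$labels > 0) * 1L,
        target$grid)
    segs <- list(); warped <- list(); ids <- character(0)
    log <- list()
    for (s in usable) {
      t0 <- proc.time()[["elapsed"]]
      res <- tryCatch({
        tf <- register(target$modalities$T1, s$modalities$T1,
                       config$nonrigid,
                       fixed_mask = reg_mask, moving_mask = s$roi_mask)
        seg_p <- apply_transform(effective_segmentation(s), tf,
                                 target_grid = target$grid)
        mods_p <- lapply(s$modalities, apply_transform, tf = tf,
                         target_grid = target$grid)
        list(seg = seg_p, mods = mods_p)
      }, error = function(e) e)
      elapsed <- proc.time()[["elapsed"]] - t0
      if (inherits(res, "error")) {
        warning("atlas '", s$id, "' excluded: ", conditionMessage(res))
        log[[s$id]] <- list(status = "excluded",
                            message = conditionMessage(res),
                            seconds = elapsed)
      } else {
        segs[[length(segs) + 1L]] <- res$seg
        warped[[length(warped) + 1L]] <- res$mods
        ids <- c(ids, s$id)
        log[[s$id]] <- list(status = "ok", seconds = elapsed)
      }
    }
    if (!length(segs)) stop("every atlas registration failed")
    stack <- propagated_stack(segs, atlas_ids = ids,
                              warped_modalities = warped,
                              target_modalities = target$modalities)
    fused <- switch(config$fusion$method,
                    MV = majority_voting(stack, config$fusion),
                    STAPLE = staple(stack, config$fusion)$fused,
                    STEPS = {
                      f <- steps(stack, config$fusion)
                      attr(f, "fit") <- NULL
                      f
                    })
    structure(list(segmentation = fused, stack = stack,
                   provenance = list(
                     target_id = target$id, atlas_ids = ids,
                     fusion_method = config$fusion$method,
                     fusion_modalities = config$fusion$modalities,
                     seed = config$seed, atlases = log,
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
              class = "segmentation_result")
  })
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("segmentation_result for '%s': %d atlas(es), fusion %s\n",
              x$provenance$target_id, length(x$provenance$atlas_ids),
              x$provenance$fusion_method))
  invisible(x)
}

#' One round of iterative atlas refinement
#'
#' Re-segments the named subject from all other subjects and stores the
#' fused result as a new automatic layer alongside any manual
#' segmentation, bumping the subject's version tag. Manual edits are
#' external events (layers dropped in by the annotator), never computed
#' here; repeating rounds without new manual input reproduces the same
#' automatic layer.
#'
#' @param atlas a [multi_atlas] with >= 2 subjects.
#' @param subject_id id of the subject to re-segment.
#' @param config a [pipeline_config].
#' @return the updated [multi_atlas].
#' @export
iterative_refinement_round <- function(atlas, subject_id,
                                       config = pipeline_config()) {
  if (length(atlas$subjects) < 2L) stop("need at least 2 subjects")
  idx <- match(subject_id, vapply(atlas$subjects, `[[`, "", "id"))
  if (is.na(idx)) stop("unknown subject id: ", subject_id)
  subject <- atlas$subjects[[idx]]
  others <- multi_atlas(atlas$subjects[-idx], atlas$taxonomy)
  res <- segment_new_subject(subject, others, config)
  version <- subject$version + 1L
  layer_name <- sprintf("auto_round%d", version)
  if (layer_name %in% names(subject$auto_layers))
    stop("version collision: layer ", layer_name, " already exists")
  subject$auto_layers[[layer_name]] <- res$segmentation
  subject$version <- version
  atlas$subjects[[idx]] <- subject
  atlas$provenance[[length(atlas$provenance) + 1L]] <-
    list(round = version, subject = subject_id,
         provenance = res$provenance)
  atlas
}

#' Leave-one-out cross validation of the automatic segmentation
#'
#' Each subject is segmented automatically from the remaining subjects
#' and compared against its stored segmentation with all four metrics,
#' per macro-region. Returns the tidy per-subject table plus the
#' box-plot statistics (median, interquartile range, min, max) per
#' macro-region and metric.
#'
#' @param atlas a [multi_atlas] with >= 3 segmented subjects.
#' @param config a [pipeline_config].
#' @param macro_map a [macro_region_map]; metrics are computed on the
#'   macro-collapsed segmentations.
#' @param metrics a [metric_params].
#' @return object of class `loo_report`: `table` (long data.frame with
#'   columns subject, label_id, label_name, metric, value) and `summary`
#'   (per macro-region/metric median, IQR, min, max).
#' @export
loo_cross_validation <- function(atlas, config = pipeline_config(),
                                 macro_map = NULL,
                                 metrics = metric_params()) {
  n <- length(atlas$subjects)
  if (n < 3L) stop("leave-one-out needs at least 3 subjects")
  rows <- list()
  for (idx in seq_len(n)) {
    subject <- atlas$subjects[[idx]]
    if (is.null(subject$segmentation)) next
    others <- multi_atlas(atlas$subjects[-idx], atlas$taxonomy)
    res <- segment_new_subject(subject, others, config)
    rep <- per_label_report(res$segmentation, subject$segmentation,
                            params = metrics, macro_map = macro_map,
                            taxonomy = atlas$taxonomy,
                            pair_id = paste0("auto_vs_manual_", subject$id))
    for (m in c("dice", "covdist", "hausdorff", "nscd"))
      rows[[length(rows) + 1L]] <-
        data.frame(subject = subject$id, label_id = rep$label_id,
                   label_name = rep$label_name, metric = m,
                   value = rep[[m]])
  }
  table <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(
    split(table, list(table$label_id, table$metric), drop = TRUE),
    function(g) {
      q <- stats::quantile(g$value, c(0.25, 0.5, 0.75), na.rm = TRUE,
                           names = FALSE)
      data.frame(label_id = g$label_id[1], label_name = g$label_name[1],
                 metric = g$metric[1], median = q[2], iqr = q[3] - q[1],
                 min = suppressWarnings(min(g$value, na.rm = TRUE)),
                 max = suppressWarnings(max(g$value, na.rm = TRUE)))
    }))
  rownames(summary) <- NULL
  structure(list(table = table, summary = summary), class = "loo_report")
}

#' @export
print.loo_report <- function(x, ...) {
  cat(sprintf("loo_report: %d subjects, %d region groups\n",
              length(unique(x$table$subject)),
              length(unique(x$table$label_id))))
  dice_med <- x$summary[x$summary$metric == "dice", ]
  if (nrow(dice_med))
    cat(sprintf("median Dice across groups: %.3f\n",
                stats::median(dice_med$median, na.rm = TRUE)))
  invisible(x)
}
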