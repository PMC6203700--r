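#' Label and intensity volumes
#'
#' A `label_volume` is an integer 3-D parcellation (0 = background) on an
#' [image_grid]; an `intensity_volume` is a real-valued 3-D image with a
#' modality tag. Both are plain lists so they stay cheap to copy and easy
#' to inspect.
#'
#' @param labels 3-D array of non-negative integers.
#' @param grid an [image_grid]; defaults to unit spacing.
#' @param taxonomy optional [taxonomy]; if given, the labels are validated
#'   against it (see `unknown`).
#' @param unknown what to do with nonzero labels absent from `taxonomy`:
#'   `"error"` (default) or `"warn"`.
#' @return object of class `label_volume` with fields `labels`, `grid`.
#' @export
label_volume <- function(labels, grid = NULL, taxonomy = NULL,
                         unknown = c("error", "warn")) {
  unknown <- match.arg(unknown)
  if (length(dim(labels)) != 3L)
    stop("labels must be a 3-D array")
  labels <- array(as.vector(labels), dim = dim(labels))
  if (is.null(grid)) grid <- image_grid(dim(labels))
  stopifnot(identical(as.integer(dim(labels)), grid$shape))
  v <- as.vector(labels)
  bad <- v[!is.finite(v) | v != round(v) | v < 0]
  if (length(bad))
    stop("non-integer label value(s): ",
         paste(utils::head(unique(bad), 5), collapse = ", "))
  storage.mode(labels) <- "integer"
  vol <- structure(list(labels = labels, grid = grid),
                   class = "label_volume")
  if (!is.null(taxonomy)) check_labels_known(vol, taxonomy, unknown)
  vol
}

check_labels_known <- function(vol, taxonomy, unknown = "error") {
  ids <- setdiff(unique(as.vector(vol$labels)), 0L)
  missing_ids <- setdiff(ids, taxonomy$entries$id)
  if (length(missing_ids)) {
    msg <- paste0("labels not in taxonomy: ",
                  paste(sort(missing_ids), collapse = ", "))
    if (unknown == "error") stop(msg) else warning(msg)
  }
  invisible(vol)
}

#' @export
print.label_volume <- function(x, ...) {
  ids <- setdiff(sort(unique(as.vector(x$labels))), 0L)
  cat(sprintf("label_volume %s: %d distinct nonzero label(s)\n",
              format(x$grid), length(ids)))
  invisible(x)
}

#' @rdname label_volume
#' @param values 3-D numeric array.
#' @param modality one of `"T1"`, `"FA"`, `"MD"`, `"V1"`, `"other"`.
#' @export
intensity_volume <- function(values, grid = NULL,
                             modality = c("other", "T1", "FA", "MD", "V1")) {
  modality <- match.arg(modality)
  if (length(dim(values)) != 3L)
    stop("values must be a 3-D array")
  values <- array(as.vector(values), dim = dim(values))
  if (is.null(grid)) grid <- image_grid(dim(values))
  stopifnot(identical(as.integer(dim(values)), grid$shape))
  storage.mode(values) <- "double"
  structure(list(values = values, grid = grid, modality = modality),
            class = "intensity_volume")
}

#' @export
print.intensity_volume <- function(x, ...) {
  cat(sprintf("intensity_volume [%s] %s, range [%.4g, %.4g]\n",
              x$modality, format(x$grid),
              min(x$values), max(x$values)))
  invisible(x)
}

grid_from_nifti <- function(img) {
  aff <- structure(as.vector(RNifti::xform(img)), dim = c(4L, 4L))
  image_grid(dim(img)[1:3], affine = aff)
}

#' Read and write label volumes as NIfTI-1
#'
#' Labels are stored with an integer datatype; reading a file whose voxel
#' data are not integer-representable is an error. The affine survives a
#' round trip to within 1e-6 and the label values bit-exactly.
#'
#' @param path file path, `.nii` or `.nii.gz`.
#' @inheritParams label_volume
#' @return [read_label_volume()] returns a [label_volume];
#'   [write_label_volume()] returns `path` invisibly.
#' @export
read_label_volume <- function(path, taxonomy = NULL,
                              unknown = c("error", "warn")) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim = dim(arr)[1:3])
  v <- as.vector(arr)
  bad <- v[!is.finite(v) | v != round(v)]
  if (length(bad))
    stop("non-integer label value(s) in ", path, ": ",
         paste(utils::head(unique(signif(bad, 6)), 5), collapse = ", "))
  label_volume(arr, grid_from_nifti(img), taxonomy = taxonomy,
               unknown = match.arg(unknown))
}

#' @rdname read_label_volume
#' @param vol a [label_volume] or [intensity_volume].
#' @export
write_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  dtype <- if (max(vol$labels) > 32767L) "int32" else "int16"
  write_nifti_with_grid(vol$labels, vol$grid, path, dtype)
}

#' @rdname read_label_volume
#' @export
read_intensity_volume <- function(path,
                                  modality = c("other", "T1", "FA", "MD", "V1")) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim = dim(arr)[1:3])
  intensity_volume(arr, grid_from_nifti(img), match.arg(modality))
}

#' @rdname read_label_volume
#' @export
write_intensity_volume <- function(vol, path) {
  stopifnot(inherits(vol, "intensity_volume"))
  write_nifti_with_grid(vol$values, vol$grid, path, "double")
}

write_nifti_with_grid <- function(arr, grid, path, datatype) {
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}
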