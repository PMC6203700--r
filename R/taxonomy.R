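#' Hierarchical label taxonomy
#'
#' A taxonomy is the table of anatomical regions a parcellation may use:
#' integer label id, name, abbreviation, side (`left` / `right` /
#' `median`), the id of the contralateral twin for sided regions, and a
#' dotted hierarchy code (e.g. "1.1" cortex, "5.3" commissural tracts).
#' Left/right twins are recorded explicitly through `pair_id` rather than
#' inferred from id parity, because median structures may carry odd or
#' even ids.
#'
#' @param entries data.frame with columns `id`, `name`, `abbrev`, `side`,
#'   `pair_id`, `level`.
#' @param name optional taxonomy name.
#' @return object of class `taxonomy`.
#' @export
taxonomy <- function(entries, name = "unnamed") {
  req <- c("id", "name", "abbrev", "side", "pair_id", "level")
  missing_cols <- setdiff(req, names(entries))
  if (length(missing_cols))
    stop("taxonomy entries lack column(s): ",
         paste(missing_cols, collapse = ", "))
  entries <- as.data.frame(entries)[req]
  entries$id <- as.integer(entries$id)
  entries$pair_id <- as.integer(entries$pair_id)
  tax <- structure(list(entries = entries, name = name), class = "taxonomy")
  validate_taxonomy(tax)
  tax
}

validate_taxonomy <- function(tax) {
  e <- tax$entries
  if (anyDuplicated(e$id))
    stop("duplicate taxonomy id(s): ",
         paste(unique(e$id[duplicated(e$id)]), collapse = ", "))
  bad_side <- setdiff(unique(e$side), c("left", "right", "median"))
  if (length(bad_side))
    stop("invalid side code(s): ", paste(bad_side, collapse = ", "))
  if (any(!grepl("^[0-9]+(\\.[0-9]+)*$", e$level)))
    stop("hierarchy codes must be dotted integers like '1.1'")
  sided <- e$side != "median"
  if (any(sided & is.na(e$pair_id)))
    stop("sided entry without pair_id: ",
         paste(e$id[sided & is.na(e$pair_id)], collapse = ", "))
  for (i in which(sided)) {
    j <- match(e$pair_id[i], e$id)
    if (is.na(j))
      stop("pair_id ", e$pair_id[i], " of entry ", e$id[i], " not in taxonomy")
    opposite <- c(left = "right", right = "left")[e$side[i]]
    if (e$side[j] != opposite)
      stop("entries ", e$id[i], "/", e$id[j], " do not have opposite sides")
    if (is.na(e$pair_id[j]) || e$pair_id[j] != e$id[i])
      stop("pairing of ", e$id[i], " and ", e$id[j], " is not mutual")
  }
  invisible(tax)
}

#' @export
print.taxonomy <- function(x, ...) {
  e <- x$entries
  cat(sprintf("taxonomy '%s': %d regions (%d paired, %d median)\n",
              x$name, nrow(e), sum(e$side != "median"),
              sum(e$side == "median")))
  invisible(x)
}

#' @export
length.taxonomy <- function(x) nrow(x$entries)

#' Load a taxonomy from JSON or by builtin name
#'
#' The packaged builtin `"neonatal_rabbit"` is the full 89-region neonatal
#' rabbit brain taxonomy. A JSON descriptor is an object with fields
#' `name` and `entries` (array of objects with `id`, `name`, `abbrev`,
#' `side`, `pair_id`, `level`; `pair_id` null for median structures).
#'
#' @param path_or_builtin file path, or `"neonatal_rabbit"`.
#' @return a validated [taxonomy].
#' @export
load_taxonomy <- function(path_or_builtin = "neonatal_rabbit") {
  if (identical(path_or_builtin, "neonatal_rabbit"))
    return(build_neonatal_rabbit_taxonomy())
  obj <- jsonlite::fromJSON(path_or_builtin, simplifyDataFrame = TRUE)
  e <- as.data.frame(obj$entries)
  if (is.null(e$pair_id)) e$pair_id <- NA_integer_
  e$pair_id[vapply(e$pair_id, is.null, TRUE)] <- NA
  e$pair_id <- suppressWarnings(as.integer(unlist(
    lapply(e$pair_id, function(p) if (is.null(p) || length(p) == 0) NA else p))))
  taxonomy(e, name = if (is.null(obj$name)) "unnamed" else obj$name)
}

#' @rdname load_taxonomy
#' @param tax a [taxonomy].
#' @param path output JSON path.
#' @export
write_taxonomy <- function(tax, path) {
  obj <- list(name = tax$name, entries = tax$entries)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Left/right label interchange map
#'
#' Returns the involution on label ids that swaps each sided region with
#' its contralateral twin and fixes median regions, used when reflecting
#' a segmentation across the mid-sagittal plane.
#'
#' @param tax a [taxonomy].
#' @return named integer vector: `map[as.character(id)]` is the swapped id.
#' @export
side_swap_map <- function(tax) {
  e <- tax$entries
  out <- ifelse(e$side == "median", e$id, e$pair_id)
  names(out) <- as.character(e$id)
  out
}

#' Export a taxonomy as an ITK-SNAP label description file
#'
#' Writes the standard ITK-SNAP text format (index, RGB, alpha,
#' visibility, mesh visibility, quoted name), with a deterministic
#' seeded color palette so repeated exports are byte-identical.
#'
#' @param tax a [taxonomy].
#' @param path output `.txt` path.
#' @param seed integer seed for the color palette.
#' @export
export_itksnap_labels <- function(tax, path, seed = 20L) {
  e <- tax$entries
  n <- nrow(e)
  cols <- with_local_seed(seed, {
    matrix(sample.int(226L, 3L * max(n, 1L), replace = TRUE) + 29L,
           ncol = 3)
  })
  lines <- c(
    "################################################",
    "# ITK-SnAP Label Description File",
    "# Fields: IDX -R- -G- -B- -A-- VIS MSH LABEL",
    "################################################",
    sprintf('%5d %5d %5d %5d %8d %3d %3d    "%s"',
            0L, 0L, 0L, 0L, 0L, 0L, 0L, "Clear Label"))
  if (n > 0) {
    ord <- order(e$id)
    lines <- c(lines, sprintf('%5d %5d %5d %5d %8d %3d %3d    "%s"',
                              e$id[ord], cols[ord, 1], cols[ord, 2],
                              cols[ord, 3], 1L, 1L, 1L, e$name[ord]))
  }
  writeLines(lines, path)
  invisible(path)
}

# run expr under a given RNG seed, restoring the caller's RNG state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
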