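#' Macro-region grouping map
#'
#' Groups base label ids into disjoint macro-regions for coarse
#' reporting. The packaged default groups the 89 neonatal rabbit regions
#' into 16 macro-regions covering the whole taxonomy.
#'
#' @param macros named list; each element is `list(name =, members =)`
#'   with `members` an integer vector of base label ids. List names are
#'   the macro ids (coercible to integer).
#' @return object of class `macro_region_map`.
#' @export
macro_region_map <- function(macros) {
  ids <- suppressWarnings(as.integer(names(macros)))
  if (any(is.na(ids)) || anyDuplicated(ids))
    stop("macro ids must be unique integers (list names)")
  all_members <- unlist(lapply(macros, `[[`, "members"))
  if (anyDuplicated(all_members))
    stop("base labels assigned to more than one macro-region: ",
         paste(unique(all_members[duplicated(all_members)]), collapse = ", "))
  macros <- lapply(macros, function(m)
    list(name = as.character(m$name), members = as.integer(m$members)))
  structure(list(macros = macros, ids = ids), class = "macro_region_map")
}

#' @export
print.macro_region_map <- function(x, ...) {
  cat(sprintf("macro_region_map: %d macro-regions over %d base labels\n",
              length(x$macros), length(macro_members(x))))
  invisible(x)
}

#' @export
length.macro_region_map <- function(x) length(x$macros)

macro_members <- function(map) unlist(lapply(map$macros, `[[`, "members"),
                                      use.names = FALSE)

#' @rdname macro_region_map
#' @export
default_macro_map <- function() build_default_macro_map()

#' @rdname macro_region_map
#' @param path JSON file: object mapping macro id to
#'   `{"name": ..., "members": [...]}`.
#' @export
load_macro_map <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  macro_region_map(lapply(obj, function(m)
    list(name = m$name, members = m$members)))
}

#' @rdname macro_region_map
#' @param map a `macro_region_map`.
#' @export
write_macro_map <- function(map, path) {
  jsonlite::write_json(map$macros, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Collapse a parcellation to macro-regions
#'
#' Replaces every voxel's base label with the id of the macro-region
#' containing it; background (0) is preserved. Any nonzero label absent
#' from the map is an error.
#'
#' @param vol a [label_volume].
#' @param map a [macro_region_map].
#' @return a [label_volume] whose nonzero values are macro ids.
#' @export
collapse_to_macro <- function(vol, map) {
  lut_max <- max(c(macro_members(map), as.vector(vol$labels))) + 1L
  lut <- rep(NA_integer_, lut_max)
  lut[1] <- 0L  # background
  for (i in seq_along(map$macros))
    lut[map$macros[[i]]$members + 1L] <- map$ids[i]
  out <- lut[vol$labels + 1L]
  if (anyNA(out)) {
    bad <- sort(unique(as.vector(vol$labels)[is.na(out)]))
    stop("labels not covered by the macro-region map: ",
         paste(bad, collapse = ", "))
  }
  label_volume(array(out, dim = dim(vol$labels)), vol$grid)
}
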