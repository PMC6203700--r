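#' Segmentation similarity metrics
#'
#' Four complementary measures between two delineations of the same
#' region: Dice overlap, covariance distance (second-moment shape
#' dissimilarity capped at `alpha`), symmetric Hausdorff distance and
#' normalized symmetric contour distance (NSCD). Distances are measured
#' between internal contours in world millimetres.
#'
#' @name seg-metrics
NULL

#' Metric parameters
#'
#' @param alpha covariance-distance cap: the score assigned to maximally
#'   dissimilar second moments (default 10).
#' @param covdist_variant `"normalized_product"` (default) normalizes the
#'   covariance inner product by the product of Frobenius norms, so
#'   identical regions score 0 and orthogonal covariances score exactly
#'   `alpha`; `"literal_sum"` divides by the sum of the norms instead.
#' @param connectivity face connectivity used for internal contours;
#'   only 6 is supported.
#' @return object of class `metric_params`.
#' @export
metric_params <- function(alpha = 10, covdist_variant = c("normalized_product",
                                                          "literal_sum"),
                          connectivity = 6L) {
  stopifnot(alpha > 0, connectivity == 6L)
  structure(list(alpha = alpha,
                 covdist_variant = match.arg(covdist_variant),
                 connectivity = 6L),
            class = "metric_params")
}

#' Extract one label's region from a parcellation
#'
#' @param vol a [label_volume].
#' @param id label id (0 selects the background).
#' @return object of class `label_region`: linear voxel indices, world
#'   point cloud (n x 3 mm), cardinality, grid.
#' @export
label_region <- function(vol, id) {
  lin <- which(vol$labels == id)
  structure(list(id = as.integer(id), lin = lin,
                 world = linear_index_world(vol$grid, lin),
                 n = length(lin), grid = vol$grid),
            class = "label_region")
}

#' @export
print.label_region <- function(x, ...) {
  cat(sprintf("label_region id=%d: %d voxel(s)\n", x$id, x$n))
  invisible(x)
}

#' Dice overlap of two regions
#'
#' `2|A1 n A2| / (|A1| + |A2|)`, in `[0, 1]`. Two empty regions give
#' `NA` (missing), not 0/0.
#'
#' @param A1,A2 [label_region]s on the same grid.
#' @return numeric scalar or `NA`.
#' @export
dice <- function(A1, A2) {
  stop_if_grid_mismatch(A1$grid, A2$grid, "regions")
  if (A1$n + A2$n == 0L) return(NA_real_)
  2 * length(intersect(A1$lin, A2$lin)) / (A1$n + A2$n)
}

region_covariance <- function(A) {
  if (A$n < 2L) return(matrix(0, 3, 3))
  stats::cov(A$world)
}

#' Covariance distance between two regions
#'
#' Treats each region as a point cloud in world space and compares their
#' 3x3 covariance matrices:
#' `alpha * (1 - Tr(c1 c2) / D)` with `D = ||c1||_F * ||c2||_F`
#' (normalized-product variant, the default: 0 for proportional
#' covariances, `alpha` exactly when `Tr(c1 c2) = 0`) or
#' `D = ||c1||_F + ||c2||_F` (literal-sum variant).
#'
#' @inheritParams dice
#' @param params a [metric_params].
#' @return value in `[0, alpha]` (normalized variant) or `NA` if either
#'   region is empty. Rank-deficient covariances are allowed with a
#'   warning.
#' @export
covariance_distance <- function(A1, A2, params = metric_params()) {
  stop_if_grid_mismatch(A1$grid, A2$grid, "regions")
  if (A1$n == 0L || A2$n == 0L) return(NA_real_)
  c1 <- region_covariance(A1)
  c2 <- region_covariance(A2)
  if (qr(c1)$rank < 3L || qr(c2)$rank < 3L)
    warning("degenerate (rank-deficient) covariance in covariance_distance")
  n1 <- sqrt(sum(c1^2)); n2 <- sqrt(sum(c2^2))
  tr <- sum(c1 * t(c2))
  if (params$covdist_variant == "normalized_product") {
    if (n1 == 0 && n2 == 0) return(0)
    if (n1 == 0 || n2 == 0) return(params$alpha)
    params$alpha * (1 - tr / (n1 * n2))
  } else {
    if (n1 + n2 == 0) return(0)
    params$alpha * (1 - tr / (n1 + n2))
  }
}

#' Internal contour of a region
#'
#' The voxels of the region having at least one 6-face neighbour outside
#' it; voxels on the grid border count the outside of the grid as
#' background. A single-voxel region is its own contour.
#'
#' @param region a [label_region].
#' @param connectivity face connectivity (6).
#' @return object of class `contour_set`: linear indices, world points.
#' @export
internal_contour <- function(region, connectivity = 6L) {
  stopifnot(connectivity == 6L)
  grid <- region$grid
  mask <- array(FALSE, dim = grid$shape)
  mask[region$lin] <- TRUE
  boundary <- array(FALSE, dim = grid$shape)
  for (r in seq_len(nrow(face_offsets))) {
    nb <- shift_array(mask, face_offsets[r, ], fill = FALSE)
    boundary <- boundary | (mask & !nb)
  }
  lin <- which(boundary)
  structure(list(id = region$id, lin = lin,
                 world = linear_index_world(grid, lin),
                 n = length(lin), grid = grid),
            class = "contour_set")
}

# for each row of P (n x 3), the minimum euclidean distance to rows of Q,
# computed in chunks to bound memory
min_point_distances <- function(P, Q, chunk = 1024L) {
  nP <- nrow(P)
  if (nP == 0L) return(numeric(0))
  q2 <- rowSums(Q^2)
  out <- numeric(nP)
  for (s in seq(1L, nP, by = chunk)) {
    e <- min(s + chunk - 1L, nP)
    Pc <- P[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Pc^2), q2, "+") - 2 * tcrossprod(Pc, Q)
    # locate the nearest point with the fast expanded form, then
    # recompute that one distance directly for full precision
    j <- max.col(-d2, ties.method = "first")
    out[s:e] <- sqrt(rowSums((Pc - Q[j, , drop = FALSE])^2))
  }
  out
}

#' Symmetric Hausdorff distance (mm)
#'
#' `max(H(A1,A2), H(A2,A1))` where `H(Ai,Aj)` is the maximum over the
#' internal contour of `Ai` of the minimal euclidean distance to the
#' internal contour of `Aj`, in world mm.
#'
#' @inheritParams covariance_distance
#' @return nonnegative mm, 0 iff the contours coincide; `NA` if either
#'   region is empty.
#' @export
hausdorff <- function(A1, A2, params = metric_params()) {
  cs <- contour_pair(A1, A2, params)
  if (is.null(cs)) return(NA_real_)
  max(max(min_point_distances(cs$p1, cs$p2)),
      max(min_point_distances(cs$p2, cs$p1)))
}

#' Normalized symmetric contour distance (mm)
#'
#' `(S(A1,A2) + S(A2,A1)) / (|dA1| + |dA2|)` where `S(Ai,Aj)` sums the
#' minimal distances from each contour voxel of `Ai` to the contour of
#' `Aj`: the outlier-robust average border discrepancy.
#'
#' @inheritParams covariance_distance
#' @return nonnegative mm; `NA` if either region is empty.
#' @export
nscd <- function(A1, A2, params = metric_params()) {
  cs <- contour_pair(A1, A2, params)
  if (is.null(cs)) return(NA_real_)
  (sum(min_point_distances(cs$p1, cs$p2)) +
     sum(min_point_distances(cs$p2, cs$p1))) /
    (nrow(cs$p1) + nrow(cs$p2))
}

contour_pair <- function(A1, A2, params) {
  stop_if_grid_mismatch(A1$grid, A2$grid, "regions")
  if (A1$n == 0L || A2$n == 0L) return(NULL)
  list(p1 = internal_contour(A1, params$connectivity)$world,
       p2 = internal_contour(A2, params$connectivity)$world)
}

#' Per-label metric report for a pair of segmentations
#'
#' Computes all four metrics for each requested label; labels empty in
#' either segmentation get `NA` rows rather than being silently scored.
#' With `macro_map` both inputs are collapsed to macro-regions before
#' measuring, giving one row per macro-region.
#'
#' @param seg1,seg2 [label_volume]s on one grid.
#' @param labels integer ids to report; default: all nonzero labels
#'   present in either input (after any macro collapse).
#' @param params a [metric_params].
#' @param macro_map optional [macro_region_map] applied first.
#' @param taxonomy optional [taxonomy] used to attach label names.
#' @param pair_id character tag recorded in the report provenance.
#' @return a `metric_report` data.frame with columns `label_id`,
#'   `label_name`, `dice`, `covdist`, `hausdorff`, `nscd`.
#' @export
per_label_report <- function(seg1, seg2, labels = NULL,
                             params = metric_params(), macro_map = NULL,
                             taxonomy = NULL, pair_id = "seg1_vs_seg2") {
  stop_if_grid_mismatch(seg1$grid, seg2$grid, "segmentations")
  if (!is.null(macro_map)) {
    seg1 <- collapse_to_macro(seg1, macro_map)
    seg2 <- collapse_to_macro(seg2, macro_map)
  }
  if (is.null(labels))
    labels <- sort(setdiff(union(unique(as.vector(seg1$labels)),
                                 unique(as.vector(seg2$labels))), 0L))
  rows <- lapply(labels, function(id) {
    A1 <- label_region(seg1, id)
    A2 <- label_region(seg2, id)
    if (A1$n == 0L || A2$n == 0L) {
      data.frame(label_id = as.integer(id), dice = NA_real_,
                 covdist = NA_real_, hausdorff = NA_real_,
                 nscd = NA_real_)
    } else {
      data.frame(label_id = as.integer(id),
                 dice = dice(A1, A2),
                 covdist = suppressWarnings(
                   covariance_distance(A1, A2, params)),
                 hausdorff = hausdorff(A1, A2, params),
                 nscd = nscd(A1, A2, params))
    }
  })
  out <- do.call(rbind, rows)
  nm <- rep(NA_character_, nrow(out))
  if (!is.null(macro_map)) {
    idx <- match(out$label_id, macro_map$ids)
    nm <- vapply(macro_map$macros[idx], function(m)
      if (is.null(m)) NA_character_ else m$name, "")
  } else if (!is.null(taxonomy)) {
    nm <- taxonomy$entries$name[match(out$label_id, taxonomy$entries$id)]
  }
  out <- cbind(label_id = out$label_id, label_name = nm,
               out[c("dice", "covdist", "hausdorff", "nscd")])
  attr(out, "pair_id") <- pair_id
  class(out) <- c("metric_report", "data.frame")
  out
}

#' Write a metric report as tidy long-format CSV
#'
#' Columns: `pair_id`, `label_id`, `label_name`, `metric`, `value`.
#'
#' @param report a `metric_report` (or a list of them).
#' @param path output CSV path.
#' @export
write_metric_report <- function(report, path) {
  reports <- if (inherits(report, "metric_report")) list(report) else report
  long <- do.call(rbind, lapply(reports, function(r) {
    pid <- attr(r, "pair_id")
    do.call(rbind, lapply(c("dice", "covdist", "hausdorff", "nscd"),
                          function(m)
      data.frame(pair_id = pid, label_id = r$label_id,
                 label_name = r$label_name, metric = m, value = r[[m]])))
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
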