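#' Synthetic phantom configuration
#'
#' The phantom emulates the structure the pipeline assumes of a real
#' cohort: a midline-symmetric, multi-region, brain-like parcellation
#' (nested ellipsoid split into lateral wedge pairs and midline shells),
#' a population of subjects derived from it by smooth random
#' diffeomorphisms plus small rigid pose jitter, multi-modal intensities
#' (per-label means, additive noise, smooth multiplicative bias field),
#' and bicommissural landmarks already in the canonical stereotaxic
#' pose. Defaults put single-atlas propagation Dice in the 0.7-0.95
#' range where label fusion is informative.
#'
#' @param shape,spacing grid dimensions and voxel size (mm).
#' @param n_subjects population size.
#' @param n_paired number of left/right wedge region pairs.
#' @param n_midline number of midline shell regions.
#' @param deformation_amplitude peak random displacement (mm).
#' @param deformation_sigma smoothness of the random velocity field
#'   (voxels).
#' @param jitter_rot,jitter_trans rigid pose jitter: peak rotation
#'   (degrees) and translation (mm).
#' @param noise_sd named additive noise SD per modality.
#' @param bias_amplitude,bias_sigma log-amplitude and smoothness
#'   (voxels) of the multiplicative bias field.
#' @param seed mandatory integer seed.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(36L, 44L, 30L),
                           spacing = c(0.4, 0.4, 0.4),
                           n_subjects = 4L, n_paired = 6L, n_midline = 3L,
                           deformation_amplitude = 1,
                           deformation_sigma = 3,
                           jitter_rot = 2, jitter_trans = 0.3,
                           noise_sd = c(T1 = 6, FA = 0.04, MD = 0.04),
                           bias_amplitude = 0.08, bias_sigma = 8,
                           seed) {
  if (missing(seed)) stop("phantom_config requires an explicit seed")
  stopifnot(deformation_amplitude >= 0, n_paired + n_midline >= 2L)
  structure(list(shape = as.integer(shape), spacing = spacing,
                 n_subjects = as.integer(n_subjects),
                 n_paired = as.integer(n_paired),
                 n_midline = as.integer(n_midline),
                 deformation_amplitude = deformation_amplitude,
                 deformation_sigma = deformation_sigma,
                 jitter_rot = jitter_rot, jitter_trans = jitter_trans,
                 noise_sd = noise_sd, bias_amplitude = bias_amplitude,
                 bias_sigma = bias_sigma, seed = as.integer(seed)),
            class = "phantom_config")
}

phantom_grid <- function(config) {
  sh <- config$shape; sp <- config$spacing
  # voxel centers symmetric about x = 0; AC-to-be at world origin,
  # brain center slightly posterior-inferior of it
  center <- c(0, -0.8, -0.8)
  origin <- center - sp * (sh - 1) / 2
  origin[1] <- -sp[1] * (sh[1] - 1) / 2
  image_grid(sh, spacing = sp, origin = origin)
}

phantom_brain_center <- function() c(0, -0.8, -0.8)

#' Build the midline-symmetric base phantom
#'
#' @param config a [phantom_config].
#' @return list with `segmentation` ([label_volume]), `taxonomy`
#'   (generated, with left/right odd/even pair metadata), `landmarks`
#'   (AC at the world origin, PC posterior-inferior at 45 degrees, so
#'   the base is already in canonical stereotaxic pose), and
#'   `roi_mask`.
#' @export
make_base_phantom <- function(config) {
  grid <- phantom_grid(config)
  sh <- grid$shape
  P <- config$n_paired; M <- config$n_midline
  pts <- voxel_to_world(grid, grid_index_matrix(sh))
  b <- phantom_brain_center()
  ext <- grid$spacing * (sh - 1) / 2
  radii <- c(0.82 * ext[1], 0.80 * ext[2], 0.80 * ext[3])
  e <- ((pts[, 1] - b[1]) / radii[1])^2 +
       ((pts[, 2] - b[2]) / radii[2])^2 +
       ((pts[, 3] - b[3]) / radii[3])^2
  inside <- e <= 1
  w <- 1.01 * grid$spacing[1]  # midline slab half-width
  midline <- inside & abs(pts[, 1]) <= w
  lateral <- inside & !midline
  lab <- integer(nrow(pts))
  # midline: M nested shells of the normalized radius
  shell <- pmin(floor(e * M) + 1L, M)
  lab[midline] <- 2L * P + shell[midline]
  # lateral: P azimuthal wedges around the brain center, per hemisphere
  theta <- atan2(pts[, 3] - b[3], pts[, 2] - b[2])
  wedge <- pmin(floor(P * (theta + pi) / (2 * pi)) + 1L, P)
  left <- pts[, 1] < 0
  lab[lateral & left] <- 2L * wedge[lateral & left] - 1L
  lab[lateral & !left] <- 2L * wedge[lateral & !left]
  seg <- label_volume(array(lab, dim = sh), grid)
  missing_ids <- setdiff(seq_len(2L * P + M),
                         unique(as.vector(seg$labels)))
  if (length(missing_ids))
    stop("phantom regions do not fit the grid; empty label id(s): ",
         paste(missing_ids, collapse = ", "))
  tax <- phantom_taxonomy(P, M)
  lm <- landmarks(ac = c(0, 0, 0),
                  pc = c(0, -3 * sqrt(2) / 2, -3 * sqrt(2) / 2),
                  plane_point = c(0, 0, 0), plane_normal = c(1, 0, 0))
  roi <- label_volume(array((e <= 1.12) * 1L, dim = sh), grid)
  list(segmentation = seg, taxonomy = tax, landmarks = lm,
       roi_mask = roi, grid = grid)
}

phantom_taxonomy <- function(P, M) {
  rows <- list()
  for (p in seq_len(P)) {
    rows[[length(rows) + 1L]] <- data.frame(
      id = c(2L * p - 1L, 2L * p),
      name = paste("Wedge", p, c("left", "right")),
      abbrev = sprintf("W%d_%s", p, c("L", "R")),
      side = c("left", "right"), pair_id = c(2L * p, 2L * p - 1L),
      level = sprintf("1.%d", p), stringsAsFactors = FALSE)
  }
  for (m in seq_len(M)) {
    rows[[length(rows) + 1L]] <- data.frame(
      id = 2L * P + m, name = paste("Midline shell", m),
      abbrev = sprintf("MS%d", m), side = "median",
      pair_id = NA_integer_, level = sprintf("2.%d", m),
      stringsAsFactors = FALSE)
  }
  taxonomy(do.call(rbind, rows), name = "phantom")
}

#' Macro-region grouping for the phantom taxonomy
#'
#' One macro-region per wedge pair (both hemispheres) plus one for all
#' midline shells.
#'
#' @param tax a phantom [taxonomy] from [make_base_phantom()].
#' @return a [macro_region_map].
#' @export
phantom_macro_map <- function(tax) {
  e <- tax$entries
  P <- sum(e$side == "left")
  macros <- list()
  for (p in seq_len(P))
    macros[[as.character(p)]] <- list(name = paste("Wedge pair", p),
                                      members = c(2L * p - 1L, 2L * p))
  macros[[as.character(P + 1L)]] <-
    list(name = "Midline", members = e$id[e$side == "median"])
  macro_region_map(macros)
}

# modality means per label id (0 = background). T1 contrasts follow the
# wedge/shell index; FA highlights the midline "fibertract" shells so a
# second channel carries genuinely complementary information.
phantom_modality_means <- function(tax) {
  e <- tax$entries
  ids <- e$id
  pair_index <- ifelse(e$side == "median", NA, (pmax(e$id, e$pair_id) / 2))
  mid_index <- cumsum(e$side == "median")
  t1 <- ifelse(e$side == "median",
               90 + 25 * mid_index[seq_along(ids)],
               70 + 140 * (pair_index %% 7) / 7)
  fa <- ifelse(e$side == "median", 0.80,
               0.10 + 0.15 * (pair_index %% 2))
  md <- ifelse(e$side == "median", 0.35,
               0.45 + 0.40 * ((pair_index + 3) %% 7) / 7)
  list(T1 = stats::setNames(c(10, t1), c(0, ids)),
       FA = stats::setNames(c(0.02, fa), c(0, ids)),
       MD = stats::setNames(c(0.95, md), c(0, ids)))
}

random_smooth_svf <- function(grid, sigma_vox, amplitude_mm) {
  sh <- grid$shape
  v <- array(stats::rnorm(prod(sh) * 3), dim = c(sh, 3))
  for (a in 1:3)
    v[, , , a] <- smooth_gaussian(v[, , , a], sigma_vox)
  mag <- sqrt(v[, , , 1]^2 + v[, , , 2]^2 + v[, , , 3]^2)
  peak <- max(mag)
  if (peak > 0) v <- v * (amplitude_mm / peak)
  svf_transform(v, grid)
}

smooth_bias_field <- function(grid, amplitude, sigma_vox) {
  b <- smooth_gaussian(array(stats::rnorm(prod(grid$shape)),
                             dim = grid$shape), sigma_vox)
  s <- stats::sd(b)
  if (s > 0) b <- b / s
  exp(amplitude * b)
}

phantom_modalities <- function(seg, means, noise_sd, bias_amplitude,
                               bias_sigma) {
  grid <- seg$grid
  out <- list()
  for (mod in names(means)) {
    mu <- means[[mod]][as.character(as.vector(seg$labels))]
    vals <- array(mu, dim = grid$shape)
    bias <- smooth_bias_field(grid, bias_amplitude, bias_sigma)
    vals <- vals * bias +
      array(stats::rnorm(prod(grid$shape), 0, noise_sd[[mod]]),
            dim = grid$shape)
    out[[mod]] <- intensity_volume(vals, grid,
                                   if (mod %in% c("T1", "FA", "MD")) mod
                                   else "other")
  }
  out
}

#' Generate a phantom population
#'
#' Each subject is the base phantom pushed through a random smooth
#' diffeomorphism (Gaussian-smoothed white-noise velocity scaled to the
#' configured peak amplitude, exponentiated by scaling and squaring)
#' composed with a small random rigid pose, with fresh multi-modal
#' intensities (per-label means, additive noise, multiplicative bias).
#' Ground-truth warps are kept for parameter-recovery tests.
#'
#' @param base output of [make_base_phantom()].
#' @param config the same [phantom_config].
#' @return a [multi_atlas] whose `ground_truth` field holds the base
#'   phantom and the per-subject transforms (subject space to base
#'   space).
#' @export
make_population <- function(base, config) {
  means <- phantom_modality_means(base$taxonomy)
  base_ids <- sort(setdiff(unique(as.vector(base$segmentation$labels)), 0L))
  with_local_seed(config$seed, {
    subjects <- list(); truths <- list()
    for (i in seq_len(config$n_subjects)) {
      svf <- random_smooth_svf(base$grid, config$deformation_sigma,
                               config$deformation_amplitude)
      ang <- config$jitter_rot * pi / 180
      rigid <- random_rigid_transform(max_angle = ang,
                                      max_shift = config$jitter_trans,
                                      center = phantom_brain_center())
      tf <- composite_transform(list(svf, rigid))
      seg_i <- apply_transform(base$segmentation, tf,
                               target_grid = base$grid)
      lost <- setdiff(base_ids, unique(as.vector(seg_i$labels)))
      if (length(lost))
        stop("deformation amplitude too large; label id(s) lost in ",
             "subject ", i, ": ", paste(lost, collapse = ", "))
      roi_i <- apply_transform(base$roi_mask, tf, target_grid = base$grid)
      mods <- phantom_modalities(seg_i, means, config$noise_sd,
                                 config$bias_amplitude, config$bias_sigma)
      lm_i <- transform_landmarks_through(base$landmarks, tf)
      subjects[[i]] <- atlas_subject(sprintf("subj%02d", i), mods,
                                     segmentation = seg_i,
                                     roi_mask = roi_i, landmarks = lm_i)
      truths[[i]] <- tf
    }
    atlas <- multi_atlas(subjects, base$taxonomy)
    atlas$ground_truth <- list(base = base, transforms = truths)
    atlas
  })
}

# landmark positions in subject space: the preimage of the base
# landmarks under the subject's (subject -> base) map
transform_landmarks_through <- function(lm, tf) {
  inv <- invert_transform(tf)
  nrm <- if (tf$kind == "composite") {
    rigids <- Filter(function(t1) t1$kind %in% c("rigid", "affine"),
                     tf$transforms)
    if (length(rigids)) solve(t(solve(rigids[[1]]$matrix[1:3, 1:3]))) %*%
      lm$plane_normal else lm$plane_normal
  } else lm$plane_normal
  landmarks(ac = as.vector(transform_points(inv, lm$ac)),
            pc = as.vector(transform_points(inv, lm$pc)),
            plane_point = as.vector(transform_points(inv, lm$plane_point)),
            plane_normal = as.vector(nrm))
}

#' Simulate raters with known performance
#'
#' Per rater and voxel: a foreground voxel keeps its true label with
#' probability `sensitivity`, a background voxel stays background with
#' probability `specificity`; erroneous voxels receive a spatially
#' adjacent label (the label found at a small random offset, or the
#' next label id if that equals the truth). Raters are independent
#' given the seed.
#'
#' @param truth a [label_volume].
#' @param sensitivity,specificity in (0.5, 1].
#' @param n_raters number of raters to simulate.
#' @param seed integer seed.
#' @return list of [label_volume]s, one per rater.
#' @export
simulate_raters <- function(truth, sensitivity, specificity, n_raters,
                            seed) {
  for (r in c(sensitivity, specificity))
    if (!(r > 0.5 && r <= 1))
      stop("sensitivity and specificity must lie in (0.5, 1]")
  grid <- truth$grid
  lab <- as.vector(truth$labels)
  V <- length(lab)
  labs <- sort(unique(lab))
  nxt <- stats::setNames(labs[c(2:length(labs), 1)], labs)  # cyclic next
  with_local_seed(seed, {
    lapply(seq_len(n_raters), function(r) {
      keep_p <- ifelse(lab > 0L, sensitivity, specificity)
      flip <- stats::runif(V) > keep_p
      out <- lab
      if (any(flip)) {
        idx <- arrayInd(which(flip), grid$shape)
        off <- matrix(sample(c(-2L, -1L, 1L, 2L), 3L * sum(flip),
                             replace = TRUE), ncol = 3)
        nb_idx <- pmin(pmax(idx + off, 1L),
                       matrix(grid$shape, sum(flip), 3, byrow = TRUE))
        nb <- truth$labels[nb_idx]
        err <- ifelse(nb != lab[flip], nb, nxt[as.character(lab[flip])])
        out[flip] <- err
      }
      label_volume(array(out, dim = grid$shape), grid)
    })
  })
}
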