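#' Registration parameters
#'
#' Controls the builtin intensity-based registration: a moments-based
#' initialization, an optional rigid/affine parameter search, and (in
#' diffeomorphic mode) a multiresolution demons-style refinement of a
#' stationary velocity field. An external registration command can be
#' substituted through `backend = "external"`.
#'
#' @param mode `"diffeomorphic"` (default), `"affine"`, or `"rigid"`.
#' @param similarity `"SSD"` (default), `"NCC"`, `"NMI"` (used in the
#'   rigid/affine search; `"LNCC"` additionally pre-normalizes the images
#'   by their local mean and standard deviation before the SVF stage).
#' @param levels multiresolution pyramid depth (>= 1).
#' @param iterations demons iterations per level (recycled to `levels`).
#' @param sigma_fluid Gaussian sigma (voxels) smoothing each update.
#' @param sigma_diffusion Gaussian sigma (voxels) smoothing the velocity
#'   field; this is the regularization weight of the deformation model.
#' @param max_step largest per-iteration voxel displacement update.
#' @param noise_gate multiple of the estimated per-level noise floor
#'   below which intensity mismatches generate no demons force.
#' @param lncc_sigma window sigma (voxels) for `"LNCC"` pre-normalization.
#' @param use_masks if TRUE and masks are supplied, forces are restricted
#'   to the fixed mask.
#' @param tol relative similarity improvement below which a level stops.
#' @param backend `"builtin"` or `"external"`.
#' @param external_cmd command template with placeholders `{fixed}`,
#'   `{moving}`, `{out}`; must write a displacement field as a NIfTI
#'   with dimensions (nx, ny, nz, 3) in world mm.
#' @return object of class `registration_params`.
#' @export
registration_params <- function(mode = c("diffeomorphic", "affine", "rigid"),
                                similarity = c("SSD", "NCC", "NMI", "LNCC"),
                                levels = 3L, iterations = c(40L, 30L, 15L),
                                sigma_fluid = 1.5, sigma_diffusion = 1,
                                max_step = 1, noise_gate = 3,
                                lncc_sigma = 3,
                                use_masks = TRUE, tol = 1e-5,
                                backend = c("builtin", "external"),
                                external_cmd = NULL) {
  stopifnot(levels >= 1L, sigma_diffusion >= 0, sigma_fluid >= 0)
  structure(list(mode = match.arg(mode), similarity = match.arg(similarity),
                 levels = as.integer(levels),
                 iterations = rep_len(as.integer(iterations), levels),
                 sigma_fluid = sigma_fluid,
                 sigma_diffusion = sigma_diffusion, max_step = max_step,
                 noise_gate = noise_gate,
                 lncc_sigma = lncc_sigma, use_masks = isTRUE(use_masks),
                 tol = tol, backend = match.arg(backend),
                 external_cmd = external_cmd),
            class = "registration_params")
}

#' Register a moving image to a fixed image
#'
#' Returns a transform with resampling semantics: applying it to the
#' moving volume with [apply_transform()] (on the fixed grid) aligns it
#' to the fixed image. The builtin backend initializes with an
#' intensity-moment (center-of-mass plus optional rigid/affine search)
#' alignment and, in diffeomorphic mode, refines with a multiresolution
#' demons scheme on a stationary velocity field.
#'
#' @param fixed,moving [intensity_volume]s.
#' @param params a [registration_params].
#' @param fixed_mask,moving_mask optional binary [label_volume]s.
#' @return an `rba_transform` mapping fixed-space world points to
#'   moving-space world points.
#' @export
register <- function(fixed, moving, params = registration_params(),
                     fixed_mask = NULL, moving_mask = NULL) {
  stopifnot(inherits(fixed, "intensity_volume"),
            inherits(moving, "intensity_volume"))
  if (params$backend == "external")
    return(register_external(fixed, moving, params))
  f <- normalize01(fixed$values, mask_arr(fixed_mask))
  m <- normalize01(moving$values, mask_arr(moving_mask))
  if (params$similarity == "LNCC") {
    f <- local_standardize(f, params$lncc_sigma)
    m <- local_standardize(m, params$lncc_sigma)
  }
  aff <- moments_initialize(fixed, moving, f, m, params,
                            mask_arr(fixed_mask), mask_arr(moving_mask))
  if (params$mode %in% c("rigid", "affine")) return(aff)
  # resample the (normalized) moving image onto the fixed grid once, then
  # estimate the residual deformation there
  mov_on_fixed <- apply_transform(
    intensity_volume(m, moving$grid), aff, target_grid = fixed$grid)
  svf <- demons_svf(f, mov_on_fixed$values, fixed$grid, params,
                    if (params$use_masks) mask_arr(fixed_mask) else NULL)
  composite_transform(list(svf, aff))
}

mask_arr <- function(mask) {
  if (is.null(mask)) return(NULL)
  if (inherits(mask, "label_volume")) mask$labels > 0 else mask > 0
}

normalize01 <- function(arr, mask = NULL) {
  v <- if (is.null(mask)) arr else arr[mask]
  lo <- stats::quantile(v, 0.01, names = FALSE)
  hi <- stats::quantile(v, 0.99, names = FALSE)
  if (hi <= lo) hi <- lo + 1
  clamp((arr - lo) / (hi - lo), 0, 1)
}

local_standardize <- function(arr, sigma) {
  mu <- smooth_gaussian(arr, sigma, normalize = TRUE)
  sd2 <- smooth_gaussian(arr^2, sigma, normalize = TRUE) - mu^2
  (arr - mu) / sqrt(pmax(sd2, 1e-6))
}

# --- moments + parameter-search initialization --------------------------

center_of_mass <- function(vol, arr, mask = NULL) {
  w <- arr - min(arr)
  if (!is.null(mask)) w <- w * mask
  idx <- grid_index_matrix(dim(arr))
  tot <- sum(w)
  if (tot <= 0) return(voxel_to_world(vol$grid, (dim(arr) + 1) / 2))
  com_vox <- colSums(idx * as.vector(w)) / tot
  voxel_to_world(vol$grid, matrix(com_vox, 1))
}

euler_rotation <- function(r) {
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- rbind(c(1, 0, 0), c(0, cx, -sx), c(0, sx, cx))
  Ry <- rbind(c(cy, 0, sy), c(0, 1, 0), c(-sy, 0, cy))
  Rz <- rbind(c(cz, -sz, 0), c(sz, cz, 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

rigid_matrix <- function(p, center) {
  R <- euler_rotation(p[4:6])
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- center - R %*% center + p[1:3]
  M
}

moments_initialize <- function(fixed, moving, f, m, params,
                               fmask, mmask) {
  com_f <- as.vector(center_of_mass(fixed, f, fmask))
  com_m <- as.vector(center_of_mass(moving, m, mmask))
  t0 <- com_m - com_f
  # search on a coarse pyramid level to keep each evaluation cheap
  fac <- max(1L, ceiling(max(fixed$grid$shape) / 24))
  fc <- downsample_arr(f, fac)
  gc <- downsample_grid(fixed$grid, fac)
  # blur the moving image with the same kernel the fixed pyramid level
  # received, so the objective compares equally band-limited images
  msm <- if (fac > 1L) smooth_gaussian(m, fac / 2, normalize = TRUE) else m
  mvol <- intensity_volume(msm, moving$grid)
  metric <- similarity_metric(params$similarity)
  objective_rigid <- function(p) {
    tf <- affine_transform(rigid_matrix(p, com_f), kind = "rigid")
    w <- apply_transform(mvol, tf, target_grid = gc)
    metric(fc, w$values)
  }
  p0 <- c(t0, 0, 0, 0)
  f0 <- objective_rigid(p0)
  opt <- stats::optim(p0, objective_rigid, method = "Nelder-Mead",
                      control = list(maxit = 300,
                                     parscale = c(rep(1, 3), rep(0.05, 3))))
  # Interpolating the moving image smooths its noise, which lowers an
  # SSD-type objective by up to the moving image's noise variance even
  # for spurious sub-voxel shifts. Only accept the searched pose if it
  # beats the moments initialization by more than that bias (plus a
  # relative margin), otherwise keep the initialization.
  hf_m <- m - smooth_gaussian(m, 1, normalize = TRUE)
  noise_floor <- if (params$similarity %in% c("SSD", "LNCC"))
    2 * stats::mad(hf_m)^2 else 0
  best <- if (f0 - opt$value > 1e-3 * abs(f0) + noise_floor)
    opt$par else p0
  tf <- affine_transform(rigid_matrix(best, com_f), kind = "rigid")
  if (params$mode == "affine") {
    M0 <- tf$matrix
    objective_affine <- function(q) {
      M <- M0
      M[1:3, 1:3] <- M0[1:3, 1:3] %*% (diag(3) + matrix(q[1:9], 3, 3))
      M[1:3, 4] <- M0[1:3, 4] + q[10:12]
      w <- apply_transform(mvol, affine_transform(M), target_grid = gc)
      metric(fc, w$values)
    }
    oq <- stats::optim(rep(0, 12), objective_affine, method = "Nelder-Mead",
                       control = list(maxit = 400,
                                      parscale = c(rep(0.05, 9), rep(1, 3))))
    M <- M0
    M[1:3, 1:3] <- M0[1:3, 1:3] %*% (diag(3) + matrix(oq$par[1:9], 3, 3))
    M[1:3, 4] <- M0[1:3, 4] + oq$par[10:12]
    tf <- affine_transform(M)
  }
  tf
}

similarity_metric <- function(name) {
  switch(name,
    SSD = ,
    LNCC = function(a, b) mean((a - b)^2),
    NCC = function(a, b) {
      if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
      -abs(stats::cor(as.vector(a), as.vector(b)))
    },
    NMI = function(a, b) -nmi_value(a, b))
}

nmi_value <- function(a, b, bins = 32L) {
  br_a <- seq(min(a), max(a), length.out = bins + 1L)
  br_b <- seq(min(b), max(b), length.out = bins + 1L)
  ia <- pmin(pmax(findInterval(a, br_a, all.inside = TRUE), 1L), bins)
  ib <- pmin(pmax(findInterval(b, br_b, all.inside = TRUE), 1L), bins)
  joint <- tabulate(ia + (ib - 1L) * bins, nbins = bins * bins)
  p <- joint / sum(joint)
  pa <- rowSums(matrix(p, bins, bins))
  pb <- colSums(matrix(p, bins, bins))
  H <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  (H(pa) + H(pb)) / max(H(p), .Machine$double.eps)
}

# --- multiresolution demons on a stationary velocity field ---------------

downsample_arr <- function(arr, f) {
  if (f == 1L) return(arr)
  s <- smooth_gaussian(arr, f / 2, normalize = TRUE)
  d <- dim(arr)
  s[seq(1L, d[1], by = f), seq(1L, d[2], by = f), seq(1L, d[3], by = f),
    drop = FALSE]
}

downsample_grid <- function(grid, f) {
  if (f == 1L) return(grid)
  A <- grid$affine
  A[1:3, 1:3] <- A[1:3, 1:3] * f
  image_grid(ceiling(grid$shape / f), affine = A)
}

central_gradient <- function(arr) {
  g <- vector("list", 3)
  for (ax in 1:3) {
    o <- c(0L, 0L, 0L); o[ax] <- 1L
    g[[ax]] <- (shift_array(arr, -o, fill = 0) -
                  shift_array(arr, o, fill = 0)) / 2
  }
  g
}

demons_svf <- function(f, m, grid, params, fmask = NULL) {
  levels <- params$levels
  v <- NULL
  for (l in seq(levels - 1L, 0L)) {
    fac <- 2L^l
    fl <- downsample_arr(f, fac)
    ml <- downsample_arr(m, fac)
    maskl <- if (!is.null(fmask))
      downsample_arr(fmask * 1, fac) > 0.01 else NULL
    d <- dim(fl)
    nvox <- prod(d)
    if (is.null(v)) {
      v <- matrix(0, nvox, 3)
    } else {
      v <- upsample_velocity(v, dprev, d)
    }
    pts <- grid_index_matrix(d)
    fvec <- as.vector(fl)
    # noise floor of this pyramid level, estimated from the
    # high-frequency residual of the fixed image; forces are gated where
    # the intensity mismatch is indistinguishable from noise, so the
    # field is not dragged around by texture in homogeneous regions
    hf <- fl - smooth_gaussian(fl, 1, normalize = TRUE)
    sig_n <- stats::mad(if (is.null(maskl)) hf else hf[maskl])
    gate <- params$noise_gate * sig_n
    gfx <- central_gradient(fl)
    last_mse <- Inf
    stall <- 0L
    for (it in seq_len(params$iterations[l + 1L])) {
      u_disp <- exp_disp_vox(v, d)
      warped <- interp_trilinear(ml, pts + u_disp)
      diff <- warped - fvec
      mse <- mean(diff^2)
      if (is.finite(last_mse) &&
          (last_mse - mse) < params$tol * max(last_mse, 1e-12)) {
        stall <- stall + 1L
        if (stall >= 3L) break
      } else stall <- 0L
      last_mse <- mse
      # symmetrized gradient (mean of fixed and warped-moving gradients)
      g <- central_gradient(array(warped, dim = d))
      for (a in 1:3) g[[a]] <- (g[[a]] + gfx[[a]]) / 2
      gn2 <- as.vector(g[[1]])^2 + as.vector(g[[2]])^2 + as.vector(g[[3]])^2
      denom <- gn2 + diff^2
      scale <- ifelse(denom > 1e-9 & abs(diff) > gate, -diff / denom, 0)
      upd <- cbind(as.vector(g[[1]]), as.vector(g[[2]]),
                   as.vector(g[[3]])) * scale
      if (!is.null(maskl)) upd <- upd * as.vector(maskl)
      nrm <- sqrt(rowSums(upd^2))
      cap <- pmin(1, params$max_step / pmax(nrm, 1e-12))
      upd <- upd * cap
      if (params$sigma_fluid > 0)
        for (a in 1:3)
          upd[, a] <- as.vector(smooth_gaussian(array(upd[, a], dim = d),
                                                params$sigma_fluid))
      v <- v + upd
      if (params$sigma_diffusion > 0)
        for (a in 1:3)
          v[, a] <- as.vector(smooth_gaussian(array(v[, a], dim = d),
                                              params$sigma_diffusion))
    }
    dprev <- d
  }
  A3 <- grid$affine[1:3, 1:3]
  svf_transform(array(v %*% t(A3), dim = c(dim(f), 3)), grid)
}

upsample_velocity <- function(v, dcoarse, dfine) {
  pts <- grid_index_matrix(dfine)
  ratio <- (dcoarse - 1) / pmax(dfine - 1, 1)
  pc <- cbind((pts[, 1] - 1) * ratio[1] + 1,
              (pts[, 2] - 1) * ratio[2] + 1,
              (pts[, 3] - 1) * ratio[3] + 1)
  out <- matrix(0, nrow(pts), 3)
  for (a in 1:3)
    out[, a] <- interp_trilinear(array(v[, a], dim = dcoarse), pc) / ratio[a]
  out
}

# --- external backend ----------------------------------------------------

register_external <- function(fixed, moving, params) {
  if (is.null(params$external_cmd))
    stop("external backend requires an external_cmd template")
  td <- tempfile("reg")
  dir.create(td)
  fp <- file.path(td, "fixed.nii.gz")
  mp <- file.path(td, "moving.nii.gz")
  op <- file.path(td, "disp.nii.gz")
  write_intensity_volume(fixed, fp)
  write_intensity_volume(moving, mp)
  cmd <- gsub("{fixed}", fp, params$external_cmd, fixed = TRUE)
  cmd <- gsub("{moving}", mp, cmd, fixed = TRUE)
  cmd <- gsub("{out}", op, cmd, fixed = TRUE)
  status <- system(cmd)
  if (status != 0L)
    stop("external registration command failed with exit status ", status)
  img <- RNifti::readNifti(op)
  arr <- as.array(img)
  if (length(dim(arr)) == 5L) arr <- array(arr, dim = dim(arr)[c(1:3, 5)])
  if (length(dim(arr)) != 4L || dim(arr)[4] != 3L)
    stop("external backend must produce an (nx, ny, nz, 3) displacement field")
  displacement_transform(arr, fixed$grid)
}

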