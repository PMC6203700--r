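#' Stack of propagated atlas segmentations
#'
#' The input to label fusion: N candidate segmentations of one target
#' subject, all resampled onto the target grid, optionally with the
#' warped atlas intensity channels and the target's own channels (needed
#' for LNCC-ranked fusion).
#'
#' @param segmentations list of [label_volume]s on one grid.
#' @param atlas_ids character ids, one per atlas.
#' @param warped_modalities optional list (one element per atlas) of
#'   named lists modality -> [intensity_volume] on the target grid.
#' @param target_modalities optional named list modality ->
#'   [intensity_volume].
#' @return object of class `propagated_stack`.
#' @export
propagated_stack <- function(segmentations, atlas_ids = NULL,
                             warped_modalities = NULL,
                             target_modalities = NULL) {
  n <- length(segmentations)
  stopifnot(n >= 1L)
  grid <- segmentations[[1]]$grid
  for (s in segmentations) stop_if_grid_mismatch(grid, s$grid,
                                                 "stack members")
  if (is.null(atlas_ids)) atlas_ids <- sprintf("atlas%02d", seq_len(n))
  stopifnot(!anyDuplicated(atlas_ids), length(atlas_ids) == n)
  structure(list(grid = grid, segmentations = segmentations,
                 atlas_ids = as.character(atlas_ids),
                 warped_modalities = warped_modalities,
                 target_modalities = target_modalities),
            class = "propagated_stack")
}

#' @export
print.propagated_stack <- function(x, ...) {
  cat(sprintf("propagated_stack: %d atlas(es) on grid %s\n",
              length(x$segmentations), format(x$grid)))
  invisible(x)
}

#' Label fusion parameters
#'
#' @param method `"MV"`, `"STAPLE"`, or `"STEPS"`.
#' @param modalities channels used for LNCC ranking (STEPS), e.g.
#'   `c("T1", "FA")`; default: every channel present in the stack.
#' @param modality_weights weights for combining per-modality LNCC maps
#'   (default: equal).
#' @param lncc_sigma Gaussian window sigma in mm for LNCC.
#' @param k number of best-ranked atlases kept per voxel (STEPS).
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   convergence tolerance (STAPLE/STEPS).
#' @param beta mean-field spatial-homogeneity weight for the STAPLE
#'   prior (0 disables the spatial term).
#' @param tie `"smallest"` (deterministic smallest label id, default) or
#'   `"random"` (seeded).
#' @param seed RNG seed used by the `"random"` tie policy.
#' @return object of class `fusion_params`.
#' @export
fusion_params <- function(method = c("MV", "STAPLE", "STEPS"),
                          modalities = NULL, modality_weights = NULL,
                          lncc_sigma = 1, k = NULL, max_iter = 30L,
                          tol = 1e-6, beta = 0,
                          tie = c("smallest", "random"), seed = 1L) {
  stopifnot(lncc_sigma > 0, tol > 0, beta >= 0)
  structure(list(method = match.arg(method), modalities = modalities,
                 modality_weights = modality_weights,
                 lncc_sigma = lncc_sigma, k = k,
                 max_iter = as.integer(max_iter), tol = tol, beta = beta,
                 tie = match.arg(tie), seed = as.integer(seed)),
            class = "fusion_params")
}

stack_label_matrix <- function(stack) {
  vapply(stack$segmentations, function(s) as.vector(s$labels),
         integer(prod(stack$grid$shape)))
}

# per-voxel argmax over a V x K score matrix with the configured tie policy
argmax_labels <- function(scores, labs, params) {
  if (params$tie == "random") {
    jit <- with_local_seed(params$seed,
                           matrix(stats::runif(length(scores), 0, 0.49),
                                  nrow(scores)))
    scores <- scores + jit
  }
  labs[max.col(scores, ties.method = "first")]
}

#' Majority-voting label fusion
#'
#' Each voxel takes the label propagated most often across the stack;
#' ties go to the smallest label id (or a seeded random choice).
#'
#' @param stack a [propagated_stack].
#' @param params a [fusion_params].
#' @return fused [label_volume].
#' @export
majority_voting <- function(stack, params = fusion_params("MV")) {
  D <- stack_label_matrix(stack)
  labs <- sort(unique(as.vector(D)))
  counts <- vapply(labs, function(l) rowSums(D == l),
                   numeric(nrow(D)))
  fused <- argmax_labels(counts, labs, params)
  label_volume(array(fused, dim = stack$grid$shape), stack$grid)
}

#' Local normalized cross-correlation map
#'
#' Voxel-wise Pearson correlation of two images inside a Gaussian window:
#' `(G(IJ) - G(I)G(J)) / sqrt(var_G(I) var_G(J))`, where `G` is the
#' boundary-renormalized Gaussian-weighted local mean with sigma given in
#' mm. Voxels where either local variance (relative to the largest local
#' variance in the image) vanishes are set to 0.
#'
#' @param I,J [intensity_volume]s on one grid.
#' @param sigma Gaussian window sigma in mm.
#' @param mask optional binary [label_volume]; outside it the map is 0.
#' @param var_tol relative variance floor below which the correlation is
#'   undefined and reported as 0.
#' @return [intensity_volume] with values in `[-1, 1]`.
#' @export
lncc_map <- function(I, J, sigma = 1, mask = NULL, var_tol = 1e-8) {
  stopifnot(inherits(I, "intensity_volume"), inherits(J, "intensity_volume"),
            sigma > 0)
  stop_if_grid_mismatch(I$grid, J$grid, "images")
  sv <- sigma / I$grid$spacing
  mi <- smooth_gaussian(I$values, sv, normalize = TRUE)
  mj <- smooth_gaussian(J$values, sv, normalize = TRUE)
  vi <- pmax(smooth_gaussian(I$values^2, sv, normalize = TRUE) - mi^2, 0)
  vj <- pmax(smooth_gaussian(J$values^2, sv, normalize = TRUE) - mj^2, 0)
  cv <- smooth_gaussian(I$values * J$values, sv, normalize = TRUE) - mi * mj
  ok <- vi > var_tol * max(vi) & vj > var_tol * max(vj)
  out <- array(0, dim = I$grid$shape)
  out[ok] <- clamp(cv[ok] / sqrt(vi[ok] * vj[ok]), -1, 1)
  if (!is.null(mask)) out[mask_arr(mask) == 0] <- 0
  intensity_volume(out, I$grid, "other")
}

# multi-modal LNCC of atlas i's warped channels against the target:
# weighted mean over the requested modalities
multimodal_lncc <- function(stack, i, params) {
  mods <- params$modalities
  if (is.null(mods)) mods <- names(stack$target_modalities)
  if (is.null(mods) || length(mods) == 0L)
    stop("STEPS requires target modalities in the stack")
  absent <- setdiff(mods, intersect(names(stack$target_modalities),
                                    names(stack$warped_modalities[[i]])))
  if (length(absent))
    stop("missing modality channel(s) for LNCC ranking: ",
         paste(absent, collapse = ", "))
  w <- params$modality_weights
  if (is.null(w)) w <- rep(1, length(mods))
  w <- w / sum(w)
  acc <- array(0, dim = stack$grid$shape)
  for (j in seq_along(mods)) {
    acc <- acc + w[j] * lncc_map(stack$target_modalities[[mods[j]]],
                                 stack$warped_modalities[[i]][[mods[j]]],
                                 sigma = params$lncc_sigma)$values
  }
  acc
}

# --- multi-label STAPLE EM ----------------------------------------------
# D: V x N observed label-index matrix (1..K); retain: V x N logical or
# NULL (all retained). Prior: per-voxel vote frequencies, optionally
# sharpened by a mean-field spatial term with weight beta.
staple_em <- function(D, labs, shape, params, retain = NULL) {
  V <- nrow(D); N <- ncol(D); K <- length(labs)
  if (is.null(retain)) retain <- matrix(TRUE, V, N)
  counts <- matrix(0, V, K)
  for (i in seq_len(N)) {
    idx <- cbind(seq_len(V), D[, i])
    add <- numeric(V); add[retain[, i]] <- 1
    counts[idx] <- counts[idx] + add
  }
  prior <- counts / pmax(rowSums(counts), 1)
  theta <- lapply(seq_len(N), function(i) {
    m <- matrix((1 - 0.9) / max(K - 1, 1), K, K)
    diag(m) <- if (K > 1) 0.9 else 1
    m
  })
  loglik <- -Inf
  loglik_trace <- numeric(0)
  w <- NULL
  converged <- FALSE
  log_prior <- log(prior)
  for (iter in seq_len(params$max_iter)) {
    lw <- log_prior
    for (i in seq_len(N)) {
      lt <- log(theta[[i]])
      contrib <- t(lt)[D[, i], , drop = FALSE]  # V x K: log theta[t, d_i]
      contrib[!retain[, i], ] <- 0
      lw <- lw + contrib
    }
    mx <- apply(lw, 1, max)
    wl <- exp(lw - mx)
    rs <- rowSums(wl)
    w <- wl / rs
    new_loglik <- sum(mx + log(rs))
    loglik_trace <- c(loglik_trace, new_loglik)
    if (is.finite(loglik) &&
        abs(new_loglik - loglik) < params$tol * abs(loglik)) {
      loglik <- new_loglik
      converged <- TRUE
      break
    }
    loglik <- new_loglik
    if (params$beta > 0) {
      sm <- w
      for (k in seq_len(K)) {
        a <- array(w[, k], dim = shape)
        nb <- array(0, dim = shape)
        for (r in seq_len(nrow(face_offsets)))
          nb <- nb + shift_array(a, face_offsets[r, ], fill = 0)
        sm[, k] <- as.vector(nb) / 6
      }
      pr <- prior * exp(params$beta * sm)
      log_prior <- log(pr / pmax(rowSums(pr), .Machine$double.xmin))
    }
    for (i in seq_len(N)) {
      th <- matrix(0, K, K)
      ri <- retain[, i]
      for (s in seq_len(K)) {
        sel <- ri & D[, i] == s
        if (any(sel)) th[, s] <- colSums(w[sel, , drop = FALSE])
      }
      th <- th + 1e-6  # row regularization for degenerate raters
      theta[[i]] <- th / rowSums(th)
    }
  }
  if (!converged)
    warning("STAPLE EM reached max_iter without converging; ",
            "returning the last iterate")
  list(w = w, theta = theta, loglik_trace = loglik_trace,
       converged = converged)
}

rater_performance <- function(theta, labs, w) {
  pi_t <- colSums(w) / nrow(w)
  lapply(theta, function(th) {
    dimnames(th) <- list(true = labs, observed = labs)
    K <- length(labs)
    sens <- diag(th)
    spec <- vapply(seq_len(K), function(l) {
      others <- setdiff(seq_len(K), l)
      denom <- sum(pi_t[others])
      if (denom == 0) return(NA_real_)
      sum(pi_t[others] * (1 - th[others, l])) / denom
    }, 0)
    names(sens) <- names(spec) <- labs
    structure(list(confusion = th, sensitivity = sens, specificity = spec),
              class = "rater_performance")
  })
}

#' @export
print.rater_performance <- function(x, ...) {
  cat(sprintf("rater_performance: mean sensitivity %.3f, mean specificity %.3f\n",
              mean(x$sensitivity, na.rm = TRUE),
              mean(x$specificity, na.rm = TRUE)))
  invisible(x)
}

#' Multi-label STAPLE fusion
#'
#' Simultaneous truth and performance level estimation: an EM algorithm
#' that alternates between (E) per-voxel posteriors over the hidden true
#' label, given each atlas's current confusion matrix and a per-voxel
#' vote-frequency prior (optionally sharpened by a mean-field spatial
#' homogeneity term with weight `beta`), and (M) re-estimating the
#' confusion matrices from the posteriors. The model log-likelihood is
#' non-decreasing across iterations.
#'
#' @inheritParams majority_voting
#' @return object of class `staple_fit`: `fused` ([label_volume]),
#'   `performance` (per-atlas [rater_performance]: confusion matrix with
#'   rows = true label, columns = observed, plus derived per-label
#'   sensitivity/specificity), `posterior` (V x K matrix), `labels`,
#'   `loglik_trace`, `converged`.
#' @export
staple <- function(stack, params = fusion_params("STAPLE")) {
  D0 <- stack_label_matrix(stack)
  if (ncol(D0) < 2L) stop("STAPLE needs at least 2 atlases")
  labs <- sort(unique(as.vector(D0)))
  D <- matrix(match(D0, labs), nrow(D0), ncol(D0))
  fit <- staple_em(D, labs, stack$grid$shape, params)
  fused <- argmax_labels(fit$w, labs, params)
  structure(list(
    fused = label_volume(array(fused, dim = stack$grid$shape), stack$grid),
    performance = rater_performance(fit$theta, labs, fit$w),
    posterior = fit$w, labels = labs,
    loglik_trace = fit$loglik_trace, converged = fit$converged,
    atlas_ids = stack$atlas_ids),
    class = "staple_fit")
}

#' @export
print.staple_fit <- function(x, ...) {
  cat(sprintf("staple_fit: %d atlases, %d labels, %d EM iterations (%s)\n",
              length(x$performance), length(x$labels),
              length(x$loglik_trace),
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' STEPS: LNCC-ranked selective STAPLE fusion
#'
#' Ranks the atlases at every voxel by the local normalized cross
#' correlation between their warped intensity channels and the target's,
#' keeps the best `k`, and runs the STAPLE EM restricted per voxel to the
#' retained atlases. With `k = N` (and `beta = 0`) this reproduces
#' [staple()] exactly. Rank ties at the k-th place retain all tied
#' atlases, so the result does not depend on atlas order.
#'
#' @inheritParams majority_voting
#' @return fused [label_volume]; the full fit (posteriors, performance,
#'   per-voxel retention) is attached as attribute `"fit"`.
#' @export
steps <- function(stack, params = fusion_params("STEPS")) {
  N <- length(stack$segmentations)
  k <- if (is.null(params$k)) N else as.integer(params$k)
  stopifnot(k >= 1L, k <= N)
  D0 <- stack_label_matrix(stack)
  labs <- sort(unique(as.vector(D0)))
  D <- matrix(match(D0, labs), nrow(D0), ncol(D0))
  retain <- NULL
  if (k < N) {
    L <- vapply(seq_len(N), function(i)
      as.vector(multimodal_lncc(stack, i, params)),
      numeric(prod(stack$grid$shape)))
    thr <- apply(L, 1, function(r) sort(r, decreasing = TRUE)[k])
    retain <- L >= thr - 1e-12
  }
  fit <- staple_em(D, labs, stack$grid$shape, params, retain = retain)
  fused <- argmax_labels(fit$w, labs, params)
  out <- label_volume(array(fused, dim = stack$grid$shape), stack$grid)
  attr(out, "fit") <- list(
    performance = rater_performance(fit$theta, labs, fit$w),
    posterior = fit$w, labels = labs, retain = retain,
    loglik_trace = fit$loglik_trace, converged = fit$converged)
  out
}

#' Run a grid of fusion configurations
#'
#' Applies every configuration in `params_grid` to the stack. The
#' default grid mirrors the atlas-construction protocol: 8 mono-modal
#' (T1) and 8 multi-modal (T1 + FA) starting points, each set being
#' {majority voting, STAPLE, STEPS at 3 window sigmas x 2 atlas-count
#' cutoffs}.
#'
#' @inheritParams majority_voting
#' @param params_grid named list of [fusion_params]; default
#'   [default_fusion_grid()].
#' @return named list of fused [label_volume]s, one per configuration.
#' @export
fuse <- function(stack, params_grid = default_fusion_grid(stack)) {
  out <- lapply(params_grid, function(p) {
    switch(p$method,
           MV = majority_voting(stack, p),
           STAPLE = staple(stack, p)$fused,
           STEPS = {
             f <- steps(stack, p)
             attr(f, "fit") <- NULL
             f
           })
  })
  names(out) <- names(params_grid)
  out
}

#' @rdname fuse
#' @param sigmas STEPS LNCC window sigmas (mm).
#' @param ks STEPS atlas-count cutoffs; default half and all-but-one.
#' @export
default_fusion_grid <- function(stack, sigmas = c(0.5, 1, 2), ks = NULL) {
  N <- length(stack$segmentations)
  if (is.null(ks)) ks <- unique(pmax(2L, c(ceiling(N / 2), N - 1L)))
  ks <- ks[ks <= N]
  sets <- list(T1 = "T1", multi = c("T1", "FA"))
  grid <- list()
  for (sn in names(sets)) {
    grid[[paste0("MV_", sn)]] <- fusion_params("MV", modalities = sets[[sn]])
    grid[[paste0("STAPLE_", sn)]] <-
      fusion_params("STAPLE", modalities = sets[[sn]])
    combos <- expand.grid(sigma = sigmas, k = ks)
    n_combo <- 6L
    for (r in seq_len(min(nrow(combos), n_combo))) {
      grid[[sprintf("STEPS_s%g_k%d_%s", combos$sigma[r],
                    combos$k[r], sn)]] <-
        fusion_params("STEPS", modalities = sets[[sn]],
                      lncc_sigma = combos$sigma[r], k = combos$k[r])
    }
  }
  grid
}
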