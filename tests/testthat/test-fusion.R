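make_stack <- function(label_arrays, grid = NULL) {
  vols <- lapply(label_arrays, function(a) label_volume(a, grid))
  propagated_stack(vols)
}

test_that("majority voting counts votes and applies the tie policy", {
  d <- c(4, 4, 2)
  a1 <- array(7L, dim = d); a2 <- array(7L, dim = d); a3 <- array(8L, dim = d)
  fused <- majority_voting(make_stack(list(a1, a2, a3)))
  expect_true(all(fused$labels == 7L))  # votes (7,7,8) -> 7
  # unanimous stack reproduces the input exactly
  set.seed(1)
  u <- array(sample(0:3, prod(d), replace = TRUE), dim = d)
  fu <- majority_voting(make_stack(list(u, u, u)))
  expect_identical(fu$labels, array(as.integer(u), dim = d))
  # two-way tie goes to the smallest label id
  ft <- majority_voting(make_stack(list(a1, a3)))
  expect_true(all(ft$labels == 7L))
})

test_that("fusion is invariant to atlas order", {
  set.seed(5)
  d <- c(6, 6, 4)
  arrs <- lapply(1:4, function(i)
    array(sample(0:2, prod(d), replace = TRUE), dim = d))
  f1 <- majority_voting(make_stack(arrs))
  f2 <- majority_voting(make_stack(rev(arrs)))
  expect_identical(f1$labels, f2$labels)
  p <- fusion_params("STAPLE", max_iter = 8L)
  s1 <- suppressWarnings(staple(make_stack(arrs), p))$fused
  s2 <- suppressWarnings(staple(make_stack(rev(arrs)), p))$fused
  expect_identical(s1$labels, s2$labels)
})

test_that("voxels of full consensus are never overturned", {
  set.seed(8)
  d <- c(8, 8, 4)
  base <- array(sample(0:2, prod(d), replace = TRUE), dim = d)
  arrs <- lapply(1:4, function(i) {
    a <- base
    flip <- sample(prod(d), 30)
    a[flip] <- (a[flip] + i) %% 3
    a
  })
  consensus <- Reduce(`&`, lapply(arrs, function(a) a == arrs[[1]]))
  stack <- make_stack(arrs)
  for (fused in list(majority_voting(stack),
                     staple(stack, fusion_params("STAPLE", max_iter = 8L))$fused))
    expect_true(all(fused$labels[consensus] == arrs[[1]][consensus]))
})

test_that("LNCC is 1 against itself, -1 against its negation, and matches the windowed oracle", {
  set.seed(3)
  d <- c(9, 9, 9)
  g <- image_grid(d)
  I <- intensity_volume(array(rnorm(prod(d)), dim = d), g)
  self <- lncc_map(I, I, sigma = 1)
  expect_true(all(abs(self$values - 1) < 1e-10))
  neg <- intensity_volume(-I$values, g)
  expect_true(all(abs(lncc_map(I, neg, sigma = 1)$values + 1) < 1e-10))
  J <- intensity_volume(array(rnorm(prod(d)), dim = d), g)
  got <- lncc_map(I, J, sigma = 1)
  for (center in list(c(5, 5, 5), c(4, 6, 5), c(2, 2, 2))) {
    expect_equal(got$values[center[1], center[2], center[3]],
                 oracle_lncc_at(I$values, J$values, center, 1),
                 tolerance = 1e-8)
  }
  # constant image: zero local variance is flagged as 0
  flat <- intensity_volume(array(1, dim = d), g)
  expect_true(all(lncc_map(I, flat, sigma = 1)$values == 0))
})

test_that("STAPLE posteriors equal an independently coded brute-force EM", {
  # 1-D toy: 20 voxels, 2 labels, 3 raters with hand-set error patterns
  truth <- c(rep(0L, 10), rep(1L, 10))
  r1 <- truth; r1[c(3, 12)] <- 1L - r1[c(3, 12)]
  r2 <- truth; r2[c(5, 11, 18)] <- 1L - r2[c(5, 11, 18)]
  r3 <- truth; r3[c(1, 9, 15, 20)] <- 1L - r3[c(1, 9, 15, 20)]
  arrs <- lapply(list(r1, r2, r3), function(r) array(r, dim = c(20, 1, 1)))
  stack <- make_stack(arrs)
  n_iter <- 6L
  fit <- suppressWarnings(
    staple(stack, fusion_params("STAPLE", max_iter = n_iter, tol = 1e-300)))
  D <- cbind(r1, r2, r3) + 1L
  oracle <- oracle_staple_em(D, K = 2L, n_iter = n_iter)
  expect_equal(unname(fit$posterior), unname(oracle$w), tolerance = 1e-8)
  for (i in 1:3)
    expect_equal(unname(fit$performance[[i]]$confusion),
                 unname(oracle$theta[[i]]), tolerance = 1e-8)
})

test_that("STAPLE on identical atlases is a fixed point with near-perfect raters", {
  set.seed(2)
  d <- c(8, 8, 4)
  u <- array(sample(0:2, prod(d), replace = TRUE), dim = d)
  fit <- staple(make_stack(list(u, u, u)), fusion_params("STAPLE", max_iter = 5L))
  expect_identical(fit$fused$labels, array(as.integer(u), dim = d))
  for (p in fit$performance)
    expect_true(all(diag(p$confusion) > 0.99))
})

test_that("STAPLE log-likelihood never decreases", {
  set.seed(14)
  cfg <- phantom_config(shape = c(20L, 24L, 16L), n_paired = 3L,
                        n_midline = 2L, seed = 14)
  base <- make_base_phantom(cfg)
  raters <- simulate_raters(base$segmentation, 0.85, 0.92, 4, seed = 9)
  fit <- suppressWarnings(staple(propagated_stack(raters),
                                 fusion_params("STAPLE", max_iter = 15L)))
  ll <- fit$loglik_trace
  expect_gte(length(ll), 2L)
  expect_true(all(diff(ll) > -1e-6 * abs(ll[-1])))
})

test_that("STEPS reduces to STAPLE at k = N and self-selects a perfect atlas at k = 1", {
  ph <- tiny_phantom(seed = 33, n_subjects = 3)
  pop <- ph$pop
  gt <- pop$ground_truth$transforms
  s1 <- pop$subjects[[1]]
  segs <- list(); warped <- list()
  for (i in 2:3) {
    tf <- composite_transform(list(gt[[1]], invert_transform(gt[[i]])))
    segs[[i - 1]] <- apply_transform(pop$subjects[[i]]$segmentation, tf,
                                     target_grid = s1$grid)
    warped[[i - 1]] <- lapply(pop$subjects[[i]]$modalities, apply_transform,
                              tf = tf, target_grid = s1$grid)
  }
  stack <- propagated_stack(segs, warped_modalities = warped,
                            target_modalities = s1$modalities)
  p <- fusion_params("STEPS", k = 2L, modalities = c("T1", "FA"),
                     max_iter = 10L)
  expect_identical(
    suppressWarnings(steps(stack, p))$labels,
    suppressWarnings(staple(stack, fusion_params("STAPLE",
                                                 max_iter = 10L)))$fused$labels)
  # target identical to atlas 2's warped channels: k = 1 picks atlas 2
  stack2 <- propagated_stack(segs, warped_modalities = warped,
                             target_modalities = warped[[2]])
  f <- suppressWarnings(steps(stack2, fusion_params("STEPS", k = 1L,
                                                    modalities = c("T1", "FA"),
                                                    max_iter = 10L)))
  roi <- segs[[2]]$labels > 0 | f$labels > 0
  expect_gt(mean(f$labels[roi] == segs[[2]]$labels[roi]), 0.999)
  # a corrupted atlas is dropped nearly everywhere inside the ROI
  set.seed(4)
  bad <- segs[[1]]; bad$labels[] <- sample(bad$labels)
  badmods <- lapply(warped[[1]], function(v) {
    v$values <- v$values + rnorm(length(v$values), 0, 3 * sd(v$values)); v
  })
  stack3 <- propagated_stack(list(segs[[2]], bad),
                             warped_modalities = list(warped[[2]], badmods),
                             target_modalities = s1$modalities)
  f3 <- suppressWarnings(steps(stack3, fusion_params("STEPS", k = 1L,
                                                     modalities = c("T1", "FA"),
                                                     max_iter = 10L)))
  fit <- attr(f3, "fit")
  roi <- as.vector(s1$roi_mask$labels > 0)
  expect_gt(mean(!fit$retain[roi, 2]), 0.99)
})

test_that("STEPS demands the modalities it ranks with", {
  d <- c(4, 4, 2)
  segs <- lapply(1:2, function(i) label_volume(array(0L, dim = d)))
  stack <- propagated_stack(segs)
  expect_error(steps(stack, fusion_params("STEPS", k = 1L,
                                          modalities = "T1")),
               "modal")
})

test_that("the default fusion grid runs 8 mono- and 8 multi-modal configurations", {
  ph <- tiny_phantom(seed = 44, n_subjects = 5,
                     deformation_amplitude = 0.4)
  pop <- ph$pop
  s1 <- pop$subjects[[1]]
  segs <- lapply(pop$subjects[2:5], `[[`, "segmentation")
  warped <- lapply(pop$subjects[2:5], `[[`, "modalities")
  stack <- propagated_stack(segs, warped_modalities = warped,
                            target_modalities = s1$modalities)
  grid <- default_fusion_grid(stack)
  expect_length(grid, 16L)
  expect_length(grep("_T1$", names(grid)), 8L)
  expect_length(grep("_multi$", names(grid)), 8L)
  out <- suppressWarnings(fuse(stack, grid))
  expect_length(out, 16L)
  expect_true(all(vapply(out, inherits, TRUE, "label_volume")))
  # a one-config grid equals calling the method directly
  single <- fuse(stack, list(mv = fusion_params("MV")))
  expect_identical(single$mv$labels, majority_voting(stack)$labels)
  # identical stack members: every configuration returns that member
  ustack <- propagated_stack(list(segs[[1]], segs[[1]], segs[[1]]),
                             warped_modalities = list(warped[[1]], warped[[1]],
                                                      warped[[1]]),
                             target_modalities = warped[[1]])
  uout <- suppressWarnings(fuse(ustack, default_fusion_grid(ustack)))
  for (o in uout) expect_identical(o$labels, segs[[1]]$labels)
})
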