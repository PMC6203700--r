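fast_reg <- registration_params(levels = 2L, iterations = c(15L, 8L))

test_that("identical subjects reproduce themselves as the template", {
  ph <- tiny_phantom(seed = 111, n_subjects = 3, deformation_amplitude = 0,
                     jitter_rot = 0, jitter_trans = 0,
                     noise_sd = c(T1 = 1e-4, FA = 1e-5, MD = 1e-5),
                     bias_amplitude = 0)
  gw <- groupwise_template(ph$pop, fast_reg, iterations = 1L)
  t1 <- ph$pop$subjects[[1]]$modalities$T1
  rng <- diff(range(t1$values))
  expect_lt(mean(abs(gw$template$values - t1$values)) / rng, 0.01)
  expect_lt(gw$mean_displacement_mm / mean(t1$grid$spacing), 0.1)
  pa <- probabilistic_labels(ph$pop, gw$transforms, gw$template$grid)
  expect_true(all(pa$probabilities %in% c(0, 1)))
})

test_that("two translated copies meet at the midpoint", {
  ph <- tiny_phantom(seed = 112, n_subjects = 1, deformation_amplitude = 0,
                     jitter_rot = 0, jitter_trans = 0,
                     noise_sd = c(T1 = 1, FA = 0.01, MD = 0.01),
                     bias_amplitude = 0)
  s <- ph$pop$subjects[[1]]
  shift <- function(t) {
    M <- diag(4); M[2, 4] <- t
    tf <- affine_transform(M)
    mods <- lapply(s$modalities, apply_transform, tf = tf)
    atlas_subject(paste0("s", t), mods,
                  segmentation = apply_transform(s$segmentation, tf),
                  roi_mask = apply_transform(s$roi_mask, tf))
  }
  pair <- multi_atlas(list(shift(+0.8), shift(-0.8)), ph$pop$taxonomy)
  gw <- groupwise_template(pair, fast_reg, iterations = 2L)
  # center of mass of the template sits at the midpoint (i.e. at the
  # unshifted subject's center of mass)
  com <- function(v) {
    w <- v$values - min(v$values)
    idx <- rabatlas:::grid_index_matrix(v$grid$shape)
    colSums(idx * as.vector(w)) / sum(w)
  }
  expect_lt(max(abs(com(gw$template) - com(s$modalities$T1))), 0.35)
  expect_lt(gw$mean_displacement_mm / mean(s$grid$spacing), 0.35)
})

test_that("template construction is insensitive to subject order", {
  ph <- tiny_phantom(seed = 113, n_subjects = 3,
                     deformation_amplitude = 0.5)
  pop <- ph$pop
  rev_pop <- multi_atlas(rev(pop$subjects), pop$taxonomy)
  gw1 <- groupwise_template(pop, fast_reg, iterations = 1L)
  gw2 <- groupwise_template(rev_pop, fast_reg, iterations = 1L)
  rng <- diff(range(gw1$template$values))
  expect_lt(max(abs(gw1$template$values - gw2$template$values)) / rng, 1e-3)
})

test_that("probabilistic label maps partition unity and count subjects", {
  ph <- tiny_phantom(seed = 114, n_subjects = 3, deformation_amplitude = 0,
                     jitter_rot = 0, jitter_trans = 0)
  pop <- ph$pop
  # 12 identical copies, one disagreeing at a single voxel
  s <- pop$subjects[[1]]
  subjects <- lapply(1:12, function(i) {
    si <- s; si$id <- sprintf("copy%02d", i); si
  })
  vox <- which(subjects[[1]]$segmentation$labels > 0)[1]
  subjects[[12]]$segmentation$labels[vox] <- 0L
  atl <- multi_atlas(subjects, pop$taxonomy)
  ident <- lapply(1:12, function(i) identity_transform())
  pa <- probabilistic_labels(atl, ident, s$grid)
  sums <- apply(pa$probabilities, 1:3, sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  disagreeing_label <- s$segmentation$labels[vox]
  j <- match(disagreeing_label, pa$labels)
  expect_equal(pa$probabilities[, , , j][vox], 11 / 12)
  expect_equal(pa$probabilities[, , , 1][vox], 1 / 12)  # background share
  expect_error(probabilistic_labels(atl, ident[1:3], s$grid),
               "one transform per subject")
})

test_that("probabilistic atlases serialize to NIfTI", {
  ph <- tiny_phantom(seed = 115, n_subjects = 2, deformation_amplitude = 0,
                     jitter_rot = 0, jitter_trans = 0)
  pop <- ph$pop
  pa <- probabilistic_labels(pop, list(identity_transform(),
                                       identity_transform()),
                             pop$subjects[[1]]$grid)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_probabilistic_atlas(pa, path)
  arr <- as.array(RNifti::readNifti(path))
  expect_equal(dim(arr), c(pop$subjects[[1]]$grid$shape, length(pa$labels)))
  expect_equal(max(abs(apply(arr, 1:3, sum) - 1)), 0, tolerance = 1e-6)
})
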