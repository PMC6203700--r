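test_that("the base phantom is symmetric, complete, and deterministic", {
  cfg <- phantom_config(seed = 17)
  base <- make_base_phantom(cfg)
  ids <- sort(setdiff(unique(as.vector(base$segmentation$labels)), 0L))
  expect_equal(length(ids), 2L * cfg$n_paired + cfg$n_midline)
  # mirror + label swap leaves the base invariant
  flipped <- flip_hemisphere_segmentation(
    base$segmentation, base$taxonomy,
    plane = list(point = c(0, 0, 0), normal = c(1, 0, 0)))
  expect_identical(flipped$labels, base$segmentation$labels)
  # generated taxonomy passes validation and follows odd/even sides
  e <- base$taxonomy$entries
  expect_true(all(e$id[e$side == "left"] %% 2 == 1))
  expect_true(all(e$id[e$side == "right"] %% 2 == 0))
  # determinism
  base2 <- make_base_phantom(phantom_config(seed = 17))
  expect_identical(base2$segmentation$labels, base$segmentation$labels)
  # landmarks are already canonical: reorientation is the identity
  tf <- stereotaxic_transform(base$landmarks)
  expect_lt(max(abs(tf$matrix - diag(4))), 1e-9)
  expect_equal(bicommissural_angle(base$landmarks), 45, tolerance = 1e-9)
})

test_that("zero deformation and jitter reproduce the base in every subject", {
  cfg <- phantom_config(n_subjects = 3, deformation_amplitude = 0,
                        jitter_rot = 0, jitter_trans = 0, seed = 21)
  base <- make_base_phantom(cfg)
  pop <- make_population(base, cfg)
  for (s in pop$subjects)
    expect_identical(s$segmentation$labels, base$segmentation$labels)
})

test_that("default deformations conserve every label and are seeded", {
  cfg <- phantom_config(n_subjects = 2, seed = 31)
  base <- make_base_phantom(cfg)
  pop <- make_population(base, cfg)
  base_ids <- sort(setdiff(unique(as.vector(base$segmentation$labels)), 0L))
  for (s in pop$subjects)
    expect_true(all(base_ids %in% as.vector(s$segmentation$labels)))
  pop2 <- make_population(base, cfg)
  expect_identical(pop2$subjects[[1]]$segmentation$labels,
                   pop$subjects[[1]]$segmentation$labels)
  expect_identical(pop2$subjects[[1]]$modalities$T1$values,
                   pop$subjects[[1]]$modalities$T1$values)
  pop3 <- make_population(base, phantom_config(n_subjects = 2, seed = 32))
  expect_false(identical(pop3$subjects[[1]]$segmentation$labels,
                         pop$subjects[[1]]$segmentation$labels))
})

test_that("agreement with the base decays as the deformation amplitude grows", {
  meds <- vapply(c(0.5, 1, 2), function(amp) {
    cfg <- phantom_config(n_subjects = 1, deformation_amplitude = amp,
                          seed = 41)
    base <- make_base_phantom(cfg)
    pop <- make_population(base, cfg)
    stats::median(per_label_report(pop$subjects[[1]]$segmentation,
                                   base$segmentation)$dice)
  }, 0)
  expect_true(all(diff(meds) < 0))
})

test_that("simulated raters hit their nominal error rates", {
  cfg <- phantom_config(shape = c(48L, 52L, 42L), seed = 51)
  base <- make_base_phantom(cfg)
  truth <- base$segmentation
  expect_gt(prod(truth$grid$shape), 1e5)
  raters <- simulate_raters(truth, 0.90, 0.95, n_raters = 3, seed = 8)
  fg <- truth$labels > 0
  for (r in raters) {
    expect_equal(mean(r$labels[fg] == truth$labels[fg]), 0.90,
                 tolerance = 0.011)
    expect_equal(mean(r$labels[!fg] == truth$labels[!fg]), 0.95,
                 tolerance = 0.011)
  }
  # perfect raters copy the truth
  perfect <- simulate_raters(truth, 1, 1, n_raters = 2, seed = 8)
  for (r in perfect) expect_identical(r$labels, truth$labels)
  # different seeds: different raters, same marginal rates
  other <- simulate_raters(truth, 0.90, 0.95, n_raters = 1, seed = 9)
  expect_false(identical(other[[1]]$labels, raters[[1]]$labels))
  expect_equal(mean(other[[1]]$labels[fg] == truth$labels[fg]), 0.90,
               tolerance = 0.011)
  expect_error(simulate_raters(truth, 0.4, 0.95, 1, 1), "0.5")
})

test_that("phantom construction fails loudly when structure cannot fit", {
  expect_error(make_base_phantom(phantom_config(shape = c(6L, 6L, 4L),
                                                n_paired = 8L,
                                                n_midline = 4L, seed = 1)),
               "empty label")
  expect_error(phantom_config(), "seed")
})
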