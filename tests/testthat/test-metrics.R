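grid10 <- image_grid(c(10, 10, 10))

block_region <- function(xr, yr, zr, grid = grid10) {
  arr <- array(0L, dim = grid$shape)
  arr[xr, yr, zr] <- 1L
  label_region(label_volume(arr, grid), 1L)
}

test_that("dice matches set counting and handles empty regions", {
  A <- block_region(2:4, 2:4, 2)
  expect_equal(dice(A, A), 1)
  B <- block_region(3:5, 2:4, 2)  # shifted by one voxel: overlap 6
  expect_equal(dice(A, B), 2 * 6 / 18)
  C <- block_region(7:9, 7:9, 9)
  expect_equal(dice(A, C), 0)
  E <- block_region(integer(0), 1, 1)
  expect_true(is.na(dice(E, E)))
  expect_equal(dice(A, E), 0)
})

test_that("covariance distance caps at alpha for orthogonal degenerate clouds", {
  arr1 <- array(0L, dim = c(60, 60, 3)); arr1[6:55, 30, 2] <- 1L
  arr2 <- array(0L, dim = c(60, 60, 3)); arr2[30, 6:55, 2] <- 1L
  g <- image_grid(c(60, 60, 3))
  A1 <- label_region(label_volume(arr1, g), 1L)
  A2 <- label_region(label_volume(arr2, g), 1L)
  expect_warning(d <- covariance_distance(A1, A2), "degenerate")
  expect_equal(d, 10)
  expect_equal(suppressWarnings(covariance_distance(A1, A1)), 0)
})

test_that("covariance distance equals the dense-matrix oracle", {
  set.seed(42)
  for (rep in 1:10) {
    m1 <- random_blob_mask(c(15, 15, 15), n_seeds = 4, grow = 50)
    m2 <- random_blob_mask(c(15, 15, 15), n_seeds = 4, grow = 50)
    g <- image_grid(c(15, 15, 15), spacing = c(0.5, 0.5, 0.5))
    A1 <- mask_region(m1, g); A2 <- mask_region(m2, g)
    expect_equal(suppressWarnings(covariance_distance(A1, A2)),
                 oracle_covdist(m1, m2, g), tolerance = 1e-10)
  }
})

test_that("literal-sum variant implements the sum-normalized formula", {
  set.seed(7)
  m1 <- random_blob_mask(c(12, 12, 12), 3, 30)
  m2 <- random_blob_mask(c(12, 12, 12), 3, 30)
  g <- image_grid(c(12, 12, 12))
  c1 <- stats::cov(mask_world_points(m1, g))
  c2 <- stats::cov(mask_world_points(m2, g))
  expected <- 10 * (1 - sum(diag(c1 %*% c2)) /
                      (norm(c1, "F") + norm(c2, "F")))
  got <- suppressWarnings(covariance_distance(
    mask_region(m1, g), mask_region(m2, g),
    metric_params(covdist_variant = "literal_sum")))
  expect_equal(got, expected, tolerance = 1e-10)
})

test_that("internal contour follows the 6-face neighbourhood definition", {
  cube <- block_region(4:6, 4:6, 4:6)
  expect_equal(internal_contour(cube)$n, 26L)  # all but the center
  single <- block_region(5, 5, 5)
  expect_equal(internal_contour(single)$lin, single$lin)
  # full grid: out-of-grid counts as outside, so the boundary slab remains
  full <- block_region(1:10, 1:10, 1:10)
  expect_equal(internal_contour(full)$n, 1000L - 8L^3)
})

test_that("hausdorff and nscd reproduce hand-computed point cases", {
  a <- block_region(2, 5, 5)
  b <- block_region(5, 5, 5)  # 3 voxels apart, 1 mm spacing
  expect_equal(hausdorff(a, b), 3)
  expect_equal(nscd(a, b), 3)  # (d + d) / (1 + 1)
  expect_equal(hausdorff(a, a), 0)
  expect_equal(nscd(a, a), 0)
  e <- block_region(integer(0), 1, 1)
  expect_true(is.na(hausdorff(a, e)))
  expect_true(is.na(nscd(a, e)))
})

test_that("contour distances equal the exhaustive oracle on random masks", {
  set.seed(11)
  g <- image_grid(c(14, 14, 14), spacing = c(0.3, 0.4, 0.5))
  for (rep in 1:15) {
    m1 <- random_blob_mask(c(14, 14, 14), 3, 25)
    m2 <- random_blob_mask(c(14, 14, 14), 3, 25)
    A1 <- mask_region(m1, g); A2 <- mask_region(m2, g)
    o <- oracle_hd_nscd(m1, m2, g)
    expect_equal(hausdorff(A1, A2), o$hd, tolerance = 1e-9)
    expect_equal(nscd(A1, A2), o$nscd, tolerance = 1e-9)
    expect_equal(dice(A1, A2), oracle_dice(m1, m2))
  }
})

test_that("metric axioms hold on random fixtures", {
  set.seed(23)
  p <- metric_params()
  for (rep in 1:10) {
    m1 <- random_blob_mask(c(12, 12, 12), 3, 30)
    m2 <- random_blob_mask(c(12, 12, 12), 3, 30)
    g <- image_grid(c(12, 12, 12))
    A1 <- mask_region(m1, g); A2 <- mask_region(m2, g)
    expect_equal(dice(A1, A2), dice(A2, A1))
    expect_equal(hausdorff(A1, A2, p), hausdorff(A2, A1, p))
    expect_equal(nscd(A1, A2, p), nscd(A2, A1, p))
    expect_equal(suppressWarnings(covariance_distance(A1, A2, p)),
                 suppressWarnings(covariance_distance(A2, A1, p)))
    expect_lte(nscd(A1, A2, p), hausdorff(A1, A2, p))
    expect_gte(suppressWarnings(covariance_distance(A1, A2, p)), 0)
    expect_lte(suppressWarnings(covariance_distance(A1, A2, p)), 10)
  }
})

test_that("translating a region away never decreases HD or NSCD", {
  base <- block_region(3:5, 4:6, 4:6)
  prev_hd <- -1; prev_nscd <- -1
  for (shift in 0:4) {
    moved <- block_region(3:5 + shift, 4:6, 4:6)
    hd <- hausdorff(base, moved)
    nc <- nscd(base, moved)
    expect_gte(hd, prev_hd)
    expect_gte(nc, prev_nscd)
    prev_hd <- hd; prev_nscd <- nc
  }
})

test_that("per-label reports carry sentinels, filters, and macro collapse", {
  tax <- load_taxonomy("neonatal_rabbit")
  ids <- tax$entries$id
  # two parcellations of an 89-voxel strip: 48 labels agree, 41 are
  # displaced to non-overlapping positions
  arr1 <- array(0L, dim = c(89, 2, 1)); arr1[, 1, 1] <- ids
  arr2 <- arr1
  moved <- ids[49:89]
  arr2[arr2 %in% moved] <- 0L
  arr2[match(moved, ids), 2, 1] <- moved
  seg1 <- label_volume(arr1); seg2 <- label_volume(arr2)
  rep <- per_label_report(seg1, seg2, labels = ids, taxonomy = tax)
  expect_equal(nrow(rep), 89L)
  kept <- rep[!is.na(rep$dice) & (1 - rep$dice) < 1, ]
  expect_equal(nrow(kept), 48L)
  expect_true(all(kept$dice == 1))
  # self comparison: dice 1, all distances 0
  self <- per_label_report(seg1, seg1, labels = ids)
  expect_true(all(self$dice == 1))
  expect_true(all(self$hausdorff == 0 & self$nscd == 0))
  # macro collapse yields one row per macro-region
  repm <- per_label_report(seg1, seg1, macro_map = default_macro_map())
  expect_equal(nrow(repm), 16L)
  # grid mismatch is an error
  other <- label_volume(arr1, image_grid(c(89, 2, 1), spacing = c(2, 1, 1)))
  expect_error(per_label_report(seg1, other), "grid")
})

test_that("metric reports export as tidy CSV", {
  arr <- array(0L, dim = c(5, 5, 2)); arr[2:3, 2:3, 1] <- 7L
  seg <- label_volume(arr)
  rep <- per_label_report(seg, seg, pair_id = "self")
  path <- withr::local_tempfile(fileext = ".csv")
  write_metric_report(rep, path)
  tidy <- read.csv(path)
  expect_named(tidy, c("pair_id", "label_id", "label_name", "metric", "value"))
  expect_equal(nrow(tidy), 4L)
  expect_equal(tidy$value[tidy$metric == "dice"], 1)
})
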