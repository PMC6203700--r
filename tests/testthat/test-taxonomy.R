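test_that("builtin taxonomy reproduces the full region table", {
  tax <- load_taxonomy("neonatal_rabbit")
  e <- tax$entries
  expect_equal(nrow(e), 89L)
  expect_false(anyDuplicated(e$id) > 0)
  # spot checks: paired cortical area, unpaired median structures
  expect_equal(e$side[e$id == 7], "left")
  expect_equal(e$pair_id[e$id == 7], 8L)
  expect_equal(e$side[e$id == 77], "median")   # basal forebrain, odd id
  expect_equal(e$side[e$id == 78], "median")   # septum, even id
  expect_equal(e$side[e$id == 218], "median")  # corpus callosum, even id
  expect_equal(e$side[e$id == 121], "median")
  # left/right odd/even convention holds for every paired entry
  paired <- e[e$side != "median", ]
  expect_true(all(paired$id[paired$side == "left"] %% 2 == 1))
  expect_true(all(paired$id[paired$side == "right"] %% 2 == 0))
})

test_that("taxonomy validation rejects malformed descriptors", {
  e <- load_taxonomy("neonatal_rabbit")$entries
  dup <- rbind(e, e[1, ])
  expect_error(taxonomy(dup), "duplicate")
  broken <- e
  broken$pair_id[broken$id == 7] <- NA_integer_
  expect_error(taxonomy(broken), "without pair_id")
  bad_side <- e
  bad_side$side[1] <- "sinister"
  expect_error(taxonomy(bad_side), "side")
  not_mutual <- e
  not_mutual$pair_id[not_mutual$id == 8] <- 10L
  expect_error(taxonomy(not_mutual), "mutual|opposite")
})

test_that("taxonomy JSON round-trips", {
  tax <- load_taxonomy("neonatal_rabbit")
  path <- withr::local_tempfile(fileext = ".json")
  write_taxonomy(tax, path)
  tax2 <- load_taxonomy(path)
  expect_equal(tax2$entries, tax$entries)
})

test_that("side swap map is a side-consistent involution", {
  tax <- load_taxonomy("neonatal_rabbit")
  sw <- side_swap_map(tax)
  expect_equal(unname(sw["7"]), 8L)
  expect_equal(unname(sw["8"]), 7L)
  expect_equal(unname(sw["121"]), 121L)
  ids <- as.integer(names(sw))
  expect_equal(unname(sw[as.character(sw)]), ids)  # involution
  e <- tax$entries
  mirror <- c(left = "right", right = "left", median = "median")
  side_of <- stats::setNames(e$side, e$id)
  expect_equal(unname(side_of[as.character(sw)]),
               unname(mirror[side_of[as.character(ids)]]))
})

test_that("ITK-SNAP export is complete and deterministic", {
  tax <- load_taxonomy("neonatal_rabbit")
  p1 <- withr::local_tempfile(fileext = ".txt")
  p2 <- withr::local_tempfile(fileext = ".txt")
  export_itksnap_labels(tax, p1, seed = 7)
  export_itksnap_labels(tax, p2, seed = 7)
  l1 <- readLines(p1)
  expect_identical(l1, readLines(p2))
  data_rows <- grep("^\\s*\\d", l1, value = TRUE)
  expect_length(data_rows, 90L)  # background + 89 regions
  expect_match(data_rows[1], "\"Clear Label\"")
  # empty taxonomy: background row only
  empty <- taxonomy(data.frame(id = integer(), name = character(),
                               abbrev = character(), side = character(),
                               pair_id = integer(), level = character()))
  p3 <- withr::local_tempfile(fileext = ".txt")
  export_itksnap_labels(empty, p3)
  expect_length(grep("^\\s*\\d", readLines(p3)), 1L)
})

test_that("default macro map groups the 89 regions into 16 macro-regions", {
  tax <- load_taxonomy("neonatal_rabbit")
  map <- default_macro_map()
  expect_length(map, 16L)
  members <- unlist(lapply(map$macros, `[[`, "members"))
  expect_false(anyDuplicated(members) > 0)
  expect_setequal(members, tax$entries$id)
})

test_that("collapse_to_macro relabels by group and preserves background", {
  map <- default_macro_map()
  arr <- array(0L, dim = c(4, 4, 2))
  arr[1, 1, 1] <- 223L  # internal capsule left
  arr[2, 1, 1] <- 229L  # subcortical white matter left
  arr[3, 1, 1] <- 31L   # hippocampus left
  vol <- label_volume(arr)
  out <- collapse_to_macro(vol, map)
  expect_equal(out$labels[1, 1, 1], 1L)  # corticospinal tract
  expect_equal(out$labels[2, 1, 1], 1L)
  expect_equal(out$labels[3, 1, 1], 12L) # hippocampal area
  expect_equal(out$labels[4, 1, 1], 0L)
  # volume containing every taxonomy id collapses to the 16 macro ids
  tax <- load_taxonomy("neonatal_rabbit")
  all_arr <- array(0L, dim = c(10, 10, 1))
  all_arr[seq_along(tax$entries$id)] <- tax$entries$id
  full <- collapse_to_macro(label_volume(all_arr), map)
  expect_setequal(setdiff(unique(as.vector(full$labels)), 0L), 1:16)
  # identity map leaves a volume unchanged
  idmap <- macro_region_map(stats::setNames(lapply(c(31L, 223L, 229L),
    function(i) list(name = as.character(i), members = i)),
    c(31L, 223L, 229L)))
  expect_identical(collapse_to_macro(vol, idmap)$labels, vol$labels)
  # unmapped label is an error naming the id
  bad <- label_volume(array(999L, dim = c(2, 2, 2)))
  expect_error(collapse_to_macro(bad, map), "999")
})
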