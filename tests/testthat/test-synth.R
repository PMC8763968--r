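test_that("scene synthesis is bit-for-bit deterministic in the seed", {
  p <- scene_params(preset = "wt_vesicle", seed = 77)
  a <- synthesize_scene(p)
  b <- synthesize_scene(p)
  expect_identical(a$image, b$image)
  expect_identical(a$truth, b$truth)
  c <- synthesize_scene(scene_params(preset = "wt_vesicle", seed = 78))
  expect_false(identical(a$image, c$image))
})

test_that("zero vesicle density gives an empty scene", {
  s <- synthesize_scene(scene_params(preset = "wt_vesicle",
                                     vesicle_density_per_um2 = 0, seed = 3),
                        render = FALSE)
  expect_equal(s$truth$vesicle_count, 0)
  expect_equal(nrow(s$truth$vesicle_centers), 0)
})

test_that("with no gap sectors the separation equals the baseline everywhere", {
  s <- synthesize_scene(scene_params(preset = "wt_morpho", gap_spec = list(),
                                     seed = 5), render = FALSE)
  um <- s$truth$nm_per_px / 1000
  prof <- boundary_gap_profile(s$truth$neuron_contour * um,
                               s$truth$sgc_inner_contour * um)
  expect_true(all(abs(prof - 0.03) < um)) # within one pixel
})

test_that("vesicle counts follow the Poisson law over the cytoplasm area", {
  p <- scene_params(preset = "wt_vesicle", vesicle_density_per_um2 = 10)
  counts <- vapply(1:200, function(i)
    synthesize_scene(scene_params(preset = "wt_vesicle",
                                  vesicle_density_per_um2 = 10,
                                  seed = 4000 + i),
                     render = FALSE)$truth$vesicle_count, numeric(1))
  # independent area oracle: Monte-Carlo integration of the clipped ring
  tr <- synthesize_scene(p, render = FALSE)$truth
  um <- tr$nm_per_px / 1000
  ext <- rev(tr$image_size_px) * um
  set.seed(99)
  qx <- runif(2e5, 0, ext[1]); qy <- runif(2e5, 0, ext[2])
  inring <- point_in_polygon(qx, qy, tr$sgc_outer_contour * um) &
            !point_in_polygon(qx, qy, tr$sgc_inner_contour * um)
  area_mc <- mean(inring) * prod(ext)
  expect_lt(abs(tr$cytoplasm_area_um2 - area_mc) / area_mc, 0.02)
  lambda <- 10 * area_mc
  se <- sqrt(lambda / 200)
  expect_lt(abs(mean(counts) - lambda), 3 * se)
  # dispersion index of a Poisson process is ~ 1
  disp <- var(counts) / mean(counts)
  expect_gt(disp, 0.7)
  expect_lt(disp, 1.3)
})

test_that("vesicle centers lie inside the SGC cytoplasm ring", {
  for (seed in c(2, 9)) {
    tr <- synthesize_scene(scene_params(preset = "ko_vesicle", seed = seed),
                           render = FALSE)$truth
    expect_equal(tr$vesicle_count, nrow(tr$vesicle_centers))
    expect_equal(tr$vesicle_count, length(tr$vesicle_masks))
    if (tr$vesicle_count) {
      inside <- point_in_polygon(tr$vesicle_centers[, 1], tr$vesicle_centers[, 2],
                                 tr$sgc_outer_contour) &
                !point_in_polygon(tr$vesicle_centers[, 1], tr$vesicle_centers[, 2],
                                  tr$sgc_inner_contour)
      expect_true(all(inside))
    }
  }
})

test_that("invalid scene parameters are rejected with informative errors", {
  expect_error(scene_params(nm_per_px = 0), "nm_per_px")
  expect_error(scene_params(preset = "wt_morpho", soma_axes_um = c(12, 9)),
               "does not fit the canvas")
  overlap <- list(list(center_deg = 10, extent_deg = 40, depth_um = 0.3),
                  list(center_deg = 30, extent_deg = 40, depth_um = 0.3))
  expect_error(scene_params(preset = "wt_morpho", gap_spec = overlap),
               "overlap")
  toodeep <- list(list(center_deg = 0, extent_deg = 30, depth_um = 2))
  expect_error(scene_params(preset = "wt_morpho", gap_spec = toodeep),
               "recoverable limit")
})

test_that("rendered membranes are darker than the compartments they bound", {
  s <- synthesize_scene(scene_params(preset = "wt_morpho", seed = 12,
                                     noise_sd = 0))
  tr <- s$truth
  mid <- round(nrow(tr$neuron_contour) / 4)
  v <- tr$neuron_contour[mid, ] # (x, y) on the neuron membrane
  memb <- s$image[round(v[2]) + 1, round(v[1]) + 1]
  ctr <- tr$center_px
  interior <- s$image[round(ctr[2]) + 1, round(ctr[1]) + 1]
  expect_lt(memb, interior - 0.1)
})
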