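make_bundle <- function(net, patch_px, nm_per_px = 5) {
  structure(list(stage1 = net, stage2 = NULL, patch_px = patch_px,
                 nm_per_px = nm_per_px,
                 class_semantics = c("background", "vesicle"),
                 training_report = list(), config = list()),
            class = "model_bundle")
}

test_that("Grad-CAM maps are rectified and max-normalised for any input", {
  net <- temquant:::init_net(
    list(temquant:::layer_conv3(1, 4), temquant:::layer_relu(),
         temquant:::layer_gap(), temquant:::layer_dense(4, 2)),
    c(12, 12), seed = 3)
  b <- make_bundle(net, 12)
  set.seed(8)
  for (k in 1:5) {
    m <- grad_cam(b, matrix(runif(144), 12, 12))
    expect_true(all(m$scores >= 0))
    expect_true(all(m$scores <= 1))
    expect_equal(dim(m$scores), c(12, 12))
  }
  expect_error(grad_cam(b, matrix(runif(144), 12, 12), class_index = 3),
               "out of range")
})

test_that("Grad-CAM matches the closed form for a conv + GAP + linear model", {
  # with a single conv+relu block followed by global average pooling and a
  # linear head, the channel weights are W_dense[c, k] / HW, so the map is
  # proportional to relu(sum_k W_dense[c, k] * A_k)
  net <- temquant:::init_net(
    list(temquant:::layer_conv3(1, 3), temquant:::layer_relu(),
         temquant:::layer_gap(), temquant:::layer_dense(3, 2)),
    c(10, 10), seed = 11)
  b <- make_bundle(net, 10)
  set.seed(12)
  patch <- matrix(runif(100), 10, 10)
  got <- grad_cam(b, patch, class_index = 2)$scores
  fwd <- temquant:::net_forward(net, matrix(as.vector(patch), ncol = 1), 1L,
                                record_act = 2L)
  A <- matrix(fwd$act, 100, 3)
  Wd <- net$layers[[4]]$W
  ref <- pmax(A %*% (Wd[2, ] / 100), 0)
  if (max(ref) > 0) ref <- ref / max(ref)
  expect_equal(as.vector(got), as.vector(ref), tolerance = 1e-10)
})

test_that("trained Grad-CAM concentrates on true vesicle pixels", {
  bundle <- get_default_bundle()
  scenes <- lapply(1:3, function(i)
    synthesize_scene(scene_params(preset = "train_vesicle", seed = 700 + i)))
  ds <- make_patch_dataset(scenes, n_patches = 240, mode = "segment",
                           patch_px = bundle$patch_px, seed = 15)
  pos <- which(ds$labels == 2L)
  expect_gte(length(pos), 100)
  inside <- numeric(0); outside <- numeric(0)
  maps <- temquant:::grad_cam_batch(bundle$stage1,
                                    ds$patches[, pos, drop = FALSE], 2L)
  for (k in seq_along(pos)) {
    m <- as.vector(maps[[k]])
    fg <- ds$masks[, pos[k]] > 0
    inside <- c(inside, mean(m[fg]))
    outside <- c(outside, mean(m[!fg]))
  }
  expect_gt(mean(inside), mean(outside))
})
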