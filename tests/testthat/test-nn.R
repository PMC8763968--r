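test_that("backpropagation matches numerical gradients", {
  set.seed(42)
  net <- temquant:::init_net(
    list(temquant:::layer_conv3(1, 3), temquant:::layer_relu(),
         temquant:::layer_pool2(), temquant:::layer_conv3(3, 4),
         temquant:::layer_relu(), temquant:::layer_gap(),
         temquant:::layer_dense(4, 2)), c(8, 8), seed = 7)
  B <- 4L
  X <- matrix(rnorm(64 * B), 64, B)
  labels <- c(1L, 2L, 1L, 2L)
  lossfn <- function(net)
    temquant:::softmax_ce(temquant:::net_forward(net, X, B)$out, labels)$loss
  fwd <- temquant:::net_forward(net, X, B, keep_cache = TRUE)
  l <- temquant:::softmax_ce(fwd$out, labels)
  bk <- temquant:::net_backward(net, fwd, l$dlogits, B)
  set.seed(1)
  for (i in seq_along(net$layers)) {
    g <- bk$grads[[i]]
    if (is.null(g)) next
    th <- net$layers[[i]]$W
    for (j in sample(length(th), 5)) {
      eps <- 1e-5
      n1 <- net; n1$layers[[i]]$W[j] <- th[j] + eps
      n2 <- net; n2$layers[[i]]$W[j] <- th[j] - eps
      num <- (lossfn(n1) - lossfn(n2)) / (2 * eps)
      expect_lt(abs(num - g$dW[j]) / max(1e-8, abs(num) + abs(g$dW[j])), 1e-6)
    }
  }
})

test_that("a linearly separable toy problem reaches perfect validation accuracy", {
  # bright centred disk vs flat background patches
  px <- 16L
  n <- 200L
  set.seed(5)
  d2 <- outer((1:px - 8.5)^2, (1:px - 8.5)^2, "+")
  X <- matrix(0.45 + rnorm(px * px * n, 0, 0.02), px * px, n)
  lab <- rep(1:2, length.out = n)
  for (j in which(lab == 2L)) X[as.vector(d2 <= 16), j] <- X[as.vector(d2 <= 16), j] + 0.3
  ds <- structure(list(patches = X, labels = lab, masks = NULL,
                       split = rep(c("train", "validation"), c(160, 40)),
                       mode = "classify", patch_px = px, nm_per_px = 5,
                       seed = 5), class = "patch_dataset")
  b <- train_stage(ds, train_config(1, max_epoch = 50, patience = 50, seed = 2,
                                    lr = 2e-3))
  expect_equal(b$training_report$stage1$validation_accuracy, 1.0)
  expect_lte(b$training_report$stage1$best_epoch, 50)
})

test_that("label-shuffled data trains to chance-level accuracy", {
  px <- 16L
  n <- 200L
  set.seed(6)
  X <- matrix(runif(px * px * n, 0.3, 0.7), px * px, n)
  lab <- sample(rep(1:2, length.out = n)) # labels independent of pixels
  ds <- structure(list(patches = X, labels = lab, masks = NULL,
                       split = rep(c("train", "validation"), c(160, 40)),
                       mode = "classify", patch_px = px, nm_per_px = 5,
                       seed = 6), class = "patch_dataset")
  b <- train_stage(ds, train_config(1, max_epoch = 15, patience = 15, seed = 3))
  acc <- b$training_report$stage1$validation_accuracy
  expect_gte(acc, 0.4)
  expect_lte(acc, 0.75) # best-epoch selection biases slightly above chance
})

test_that("single-class datasets are rejected before training", {
  px <- 8L
  X <- matrix(runif(px * px * 20), px * px, 20)
  ds <- structure(list(patches = X, labels = rep(1L, 20), masks = NULL,
                       split = rep(c("train", "validation"), c(16, 4)),
                       mode = "classify", patch_px = px, nm_per_px = 5,
                       seed = 1), class = "patch_dataset")
  expect_error(train_stage(ds, train_config(1)), "single class")
})

test_that("training is deterministic under a fixed seed", {
  sc <- get_small_scene()
  ds <- make_patch_dataset(sc, n_patches = 60, mode = "classify", seed = 9)
  cfg <- train_config(1, max_epoch = 3, patience = 3, seed = 4)
  b1 <- train_stage(ds, cfg)
  b2 <- train_stage(ds, cfg)
  expect_identical(b1$stage1$layers, b2$stage1$layers)
  expect_identical(b1$training_report$stage1$per_epoch,
                   b2$training_report$stage1$per_epoch)
})

test_that("augmentation limits are enforced by the config", {
  expect_error(train_config(1, resize_limit = 0.2), "augmentation bound")
  expect_error(train_config(2, resize_limit = 0.08), "augmentation bound")
  expect_error(train_config(1, shift_px = 2), "stage-2")
  expect_error(train_config(2, shift_px = 5), "limited to 2")
  expect_silent(train_config(2, resize_limit = 0.05, shift_px = 2))
})
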