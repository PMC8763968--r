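#' Training configuration for the two detector stages
#'
#' Defaults follow the detector's training regime: stage 1 (patch
#' classifier) uses a mini-batch of 25 and at most 500 epochs with
#' augmentation by random resizing up to +/-10% and reflection; stage 2
#' (segmentation network) uses a mini-batch of 100 and at most 1,000 epochs
#' with augmentation limited to +/-5% resizing plus reflection and a small
#' pixel shift (the tighter limits avoid artifacts at the few-pixel scale of
#' a vesicle). 20% of the data is held out for validation (set when the
#' dataset is built). Training stops early once validation accuracy has not
#' improved for `patience` consecutive epochs; `max_epoch` is a cap.
#'
#' @param stage 1 or 2.
#' @param mini_batch mini-batch size (default 25 for stage 1, 100 for stage 2).
#' @param max_epoch epoch cap (default 500 / 1000).
#' @param resize_limit augmentation resize bound as a fraction (default 0.10
#'   for stage 1, 0.05 for stage 2; values above the stage default are
#'   rejected).
#' @param reflect use horizontal reflection augmentation.
#' @param shift_px pixel-shift augmentation bound (stage 2 only, default 2).
#' @param lr Adam learning rate.
#' @param patience early-stopping plateau length in epochs (default 20).
#' @param min_delta minimal validation-accuracy improvement that resets the
#'   plateau counter (default 0.2%; smaller gains count as plateau but the
#'   best-epoch weights are still kept).
#' @param seed training seed (initialisation, shuffling, augmentation).
#' @param backbone `"small_cnn"` (the default 4-conv-block classifier /
#'   3-conv segmenter).
#' @return A `train_config` list.
#' @export
train_config <- function(stage, mini_batch = NULL, max_epoch = NULL,
                         resize_limit = NULL, reflect = TRUE, shift_px = NULL,
                         lr = 1e-3, patience = 20, min_delta = 2e-3,
                         seed = 1, backbone = "small_cnn") {
  stopifnot(stage %in% c(1, 2))
  lim <- if (stage == 1) 0.10 else 0.05
  cfg <- list(stage = stage,
              mini_batch = if (is.null(mini_batch)) (if (stage == 1) 25L else 100L)
                           else as.integer(mini_batch),
              max_epoch = if (is.null(max_epoch)) (if (stage == 1) 500L else 1000L)
                          else as.integer(max_epoch),
              resize_limit = if (is.null(resize_limit)) lim else resize_limit,
              reflect = isTRUE(reflect),
              shift_px = if (is.null(shift_px)) (if (stage == 1) 0L else 2L)
                         else as.integer(shift_px),
              lr = lr, patience = as.integer(patience), min_delta = min_delta,
              seed = as.numeric(seed), backbone = backbone)
  if (cfg$resize_limit > lim + 1e-12)
    stop(sprintf("resize_limit %.3f exceeds the stage-%d augmentation bound %.2f",
                 cfg$resize_limit, stage, lim))
  if (stage == 1 && cfg$shift_px != 0L)
    stop("pixel-shift augmentation is a stage-2 option")
  if (cfg$shift_px > 2L) stop("shift_px is limited to 2 px")
  if (!backbone %in% "small_cnn")
    stop("unknown backbone: ", backbone)
  class(cfg) <- "train_config"
  cfg
}

#' Train one detector stage
#'
#' Trains the stage-1 patch classifier (`classify` dataset) or the stage-2
#' per-pixel segmentation network (`segment` dataset) and stores the result
#' in a model bundle. Training is deterministic given the config seed.
#'
#' @param dataset a [make_patch_dataset()] result whose mode matches the
#'   stage (1 = classify, 2 = segment).
#' @param config a [train_config()].
#' @param bundle optional existing `model_bundle` to add the stage to.
#' @param verbose print per-epoch progress.
#' @return A `model_bundle` with this stage's network and training report
#'   (per-epoch training loss and validation accuracy) filled in.
#' @export
train_stage <- function(dataset, config, bundle = NULL, verbose = FALSE) {
  stopifnot(inherits(dataset, "patch_dataset"), inherits(config, "train_config"))
  expected_mode <- if (config$stage == 1) "classify" else "segment"
  if (dataset$mode != expected_mode)
    stop(sprintf("stage %d expects a %s dataset, got %s",
                 config$stage, expected_mode, dataset$mode))
  itr <- which(dataset$split == "train")
  iva <- which(dataset$split == "validation")
  if (length(unique(dataset$labels[itr])) < 2)
    stop("training split contains a single class; cannot train")
  if (!length(iva)) stop("dataset has no validation split")

  px <- dataset$patch_px
  net <- if (config$stage == 1) stage1_net(px, seed = config$seed)
         else stage2_net(px, seed = config$seed)

  result <- with_seed(config$seed * 15013 + config$stage, {
    state <- adam_init(net)
    best <- list(acc = -Inf, net = net, epoch = 0L)
    mark <- -Inf # plateau reference accuracy
    report <- data.frame(epoch = integer(0), train_loss = numeric(0),
                         val_accuracy = numeric(0))
    t_adam <- 0L
    plateau <- 0L
    for (epoch in seq_len(config$max_epoch)) {
      perm <- sample(itr)
      losses <- numeric(0)
      for (s in seq(1L, length(perm), by = config$mini_batch)) {
        e <- min(length(perm), s + config$mini_batch - 1L)
        ids <- perm[s:e]
        B <- length(ids)
        aug <- augment_batch(dataset$patches[, ids, drop = FALSE],
                             if (dataset$mode == "segment")
                               dataset$masks[, ids, drop = FALSE] else NULL,
                             px, config$resize_limit, config$reflect,
                             config$shift_px)
        fwd <- net_forward(net, aug$X, B, keep_cache = TRUE)
        if (dataset$mode == "classify") {
          l <- softmax_ce(fwd$out, dataset$labels[ids])
          dOut <- l$dlogits
        } else {
          HW <- px * px
          Z <- to_channel_major(fwd$out, HW, 2L, B)
          l <- softmax_ce(Z, as.integer(aug$masks) + 1L)
          dOut <- to_pixel_major(l$dlogits, HW, 2L, B)
        }
        losses <- c(losses, l$loss)
        bk <- net_backward(net, fwd, dOut, B)
        t_adam <- t_adam + 1L
        upd <- adam_step(net, bk$grads, state, t_adam, lr = config$lr)
        net <- upd$net; state <- upd$state
      }
      acc <- evaluate_net(net, dataset, iva)
      report <- rbind(report, data.frame(epoch = epoch,
                                         train_loss = mean(losses),
                                         val_accuracy = acc))
      if (verbose)
        message(sprintf("stage %d epoch %3d loss %.4f val acc %.4f",
                        config$stage, epoch, mean(losses), acc))
      if (acc > best$acc) best <- list(acc = acc, net = net, epoch = epoch)
      if (acc > mark + config$min_delta) {
        mark <- acc
        plateau <- 0L
      } else plateau <- plateau + 1L
      if (plateau >= config$patience) break
    }
    list(net = best$net, report = report, best = best)
  })

  if (is.null(bundle))
    bundle <- structure(list(stage1 = NULL, stage2 = NULL, patch_px = px,
                             nm_per_px = dataset$nm_per_px,
                             class_semantics = c("background", "vesicle"),
                             training_report = list(), config = list()),
                        class = "model_bundle")
  slot <- paste0("stage", config$stage)
  bundle[[slot]] <- result$net
  bundle$training_report[[slot]] <-
    list(per_epoch = result$report,
         validation_accuracy = result$best$acc,
         best_epoch = result$best$epoch,
         seed = config$seed)
  bundle$config[[slot]] <- unclass(config)
  bundle
}

#' Validation accuracy of a trained stage
#'
#' Classification accuracy over patches (stage 1) or over pixels (stage 2)
#' on the items given by `idx` (default: the validation split).
#'
#' @param net a `cnn_net`.
#' @param dataset the `patch_dataset` it was trained on.
#' @param idx item indices to evaluate (default validation split).
#' @return Accuracy in [0, 1].
#' @export
evaluate_net <- function(net, dataset, idx = which(dataset$split == "validation")) {
  X <- dataset$patches[, idx, drop = FALSE]
  if (dataset$mode == "classify") {
    p <- predict_proba(net, X)
    mean((p[, 2] > 0.5) + 1L == dataset$labels[idx])
  } else {
    p <- predict_pixel_proba(net, X)
    mean((p > 0.5) == (dataset$masks[, idx, drop = FALSE] > 0))
  }
}

# Random resize (about the patch centre), horizontal reflection and integer
# pixel shift, per item; bilinear for intensities, nearest for masks.
# Out-of-range source coordinates clamp to the edge.
augment_batch <- function(X, masks, px, resize_limit, reflect, shift_px) {
  B <- ncol(X)
  Xo <- X
  Mo <- masks
  ctr <- (px - 1) / 2
  out <- seq_len(px) - 1
  for (j in seq_len(B)) {
    f <- if (resize_limit > 0) stats::runif(1, 1 - resize_limit, 1 + resize_limit) else 1
    fl <- reflect && stats::runif(1) < 0.5
    dx <- if (shift_px > 0) sample(-shift_px:shift_px, 1) else 0L
    dy <- if (shift_px > 0) sample(-shift_px:shift_px, 1) else 0L
    if (f == 1 && !fl && dx == 0 && dy == 0) next
    xo <- if (fl) rev(out) else out
    xs <- ctr + (xo - ctr) / f - dx
    ys <- ctr + (out - ctr) / f - dy
    xs <- pmin(px - 1, pmax(0, xs)); ys <- pmin(px - 1, pmax(0, ys))
    P <- matrix(X[, j], px, px)
    x0 <- pmin(floor(xs), px - 2); y0 <- pmin(floor(ys), px - 2)
    fx <- xs - x0; fy <- ys - y0
    g <- function(yy, xx) P[cbind(rep(yy + 1L, times = px), rep(xx + 1L, each = px))]
    v <- g(y0, x0) * (1 - rep(fy, px)) * (1 - rep(fx, each = px)) +
         g(y0 + 1L, x0) * rep(fy, px) * (1 - rep(fx, each = px)) +
         g(y0, x0 + 1L) * (1 - rep(fy, px)) * rep(fx, each = px) +
         g(y0 + 1L, x0 + 1L) * rep(fy, px) * rep(fx, each = px)
    Xo[, j] <- v
    if (!is.null(masks)) {
      M <- matrix(masks[, j], px, px)
      Mo[, j] <- M[cbind(rep(round(ys) + 1L, times = px),
                         rep(round(xs) + 1L, each = px))]
    }
  }
  list(X = Xo, masks = Mo)
}

#' @export
print.model_bundle <- function(x, ...) {
  s <- function(nm) if (is.null(x[[nm]])) "untrained"
    else sprintf("val acc %.4f (epoch %d)",
                 x$training_report[[nm]]$validation_accuracy,
                 x$training_report[[nm]]$best_epoch)
  cat(sprintf("<model_bundle> patch %d px @ %g nm/px\n  stage1: %s\n  stage2: %s\n",
              x$patch_px, x$nm_per_px, s("stage1"), s("stage2")))
  invisible(x)
}
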