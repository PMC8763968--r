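#' Minimal convolutional network engine
#'
#' A small, fully vectorised CNN stack sufficient for the two-stage vesicle
#' detector: 3x3 "same" convolutions, 1x1 convolutions, ReLU, 2x2 max
#' pooling, global average pooling and a dense head, trained with Adam on a
#' softmax cross-entropy loss (per patch for classification, per pixel for
#' segmentation). Convolutions are evaluated as BLAS matrix products over
#' im2col gather matrices whose integer index tables are precomputed per
#' (height, width, channels, batch) shape and cached. Everything is
#' deterministic given the seed: there is no threading or nondeterministic
#' reduction order.
#'
#' Activations are stored as matrices of shape (H*W, C*B): column-major
#' equivalent of an (H*W, C, B) array. Pixels are column-major within a
#' patch (row index fastest), matching `matrix(patch_vector, H, W)`.
#'
#' @name nn_core
#' @keywords internal
NULL

# ---- shape/index cache ------------------------------------------------------

nn_cache <- new.env(parent = emptyenv())

#' Drop the cached im2col index tables
#'
#' The tables are rebuilt on demand; dropping them frees memory after large
#' training or scanning runs.
#' @return `NULL`, invisibly.
#' @export
nn_clear_cache <- function() {
  rm(list = ls(nn_cache), envir = nn_cache)
  invisible(NULL)
}

# im2col geometry for a 3x3 same-padding convolution on H x W images with C
# channels and batch B. Returns the padded length P, embed rows E (where
# unpadded pixels live inside the padded frame) and the gather index matrix
# I of dim (9C, HW*B) into the padded (P, C*B) activation matrix.
conv3_geom <- function(H, W, C, B) {
  key <- sprintf("c3_%d_%d_%d_%d", H, W, C, B)
  if (!is.null(nn_cache[[key]])) return(nn_cache[[key]])
  Hp <- H + 2L; Wp <- W + 2L; P <- Hp * Wp; HW <- H * W
  y <- rep(seq_len(H), times = W); x <- rep(seq_len(W), each = H)
  E <- (y + 1L) + Hp * x # padded position of pixel (y, x); 1-based
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  pp <- matrix(0L, 9L, HW)
  for (k in 1:9)
    pp[k, ] <- (y + 1L + offs$dy[k]) + Hp * (x + offs$dx[k])
  I <- pp[rep(1:9, times = C), rep(seq_len(HW), times = B), drop = FALSE]
  I <- I + rep(P * (0:(C - 1L)), each = 9L) # per-row channel offset
  boff <- rep(P * C * (0:(B - 1L)), each = HW)
  I <- I + matrix(boff, nrow(I), ncol(I), byrow = TRUE) # per-column batch offset
  storage.mode(I) <- "integer"
  g <- list(P = P, E = E, I = I, HW = HW, C = C, B = B)
  nn_cache[[key]] <- g
  g
}

# (HW, C*B) -> (C, HW*B) permutation and back; used by 1x1 convs, dense
# heads and output rearrangement.
to_channel_major <- function(A, HW, C, B) {
  dim(A) <- c(HW, C, B)
  A <- aperm(A, c(2, 1, 3))
  dim(A) <- c(C, HW * B)
  A
}
to_pixel_major <- function(Z, HW, C, B) {
  dim(Z) <- c(C, HW, B)
  Z <- aperm(Z, c(2, 1, 3))
  dim(Z) <- c(HW, C * B)
  Z
}

# ---- layers -----------------------------------------------------------------

layer_conv3 <- function(c_in, c_out) {
  list(type = "conv3", c_in = c_in, c_out = c_out,
       W = NULL, b = NULL, shape_in = NULL)
}
layer_conv1 <- function(c_in, c_out)
  list(type = "conv1", c_in = c_in, c_out = c_out, W = NULL, b = NULL)
layer_relu <- function() list(type = "relu")
layer_pool2 <- function() list(type = "pool2")
layer_gap <- function() list(type = "gap")
layer_dense <- function(c_in, c_out)
  list(type = "dense", c_in = c_in, c_out = c_out, W = NULL, b = NULL)

init_net <- function(layers, input_hw, seed) {
  with_seed(seed, {
    for (i in seq_along(layers)) {
      l <- layers[[i]]
      if (l$type %in% c("conv3", "conv1", "dense")) {
        fan_in <- switch(l$type, conv3 = 9L * l$c_in, conv1 = l$c_in,
                         dense = l$c_in)
        sd <- sqrt(2 / fan_in) # He initialisation
        ncolW <- switch(l$type, conv3 = 9L * l$c_in, conv1 = l$c_in,
                        dense = l$c_in)
        layers[[i]]$W <- matrix(stats::rnorm(l$c_out * ncolW, 0, sd),
                                l$c_out, ncolW)
        layers[[i]]$b <- numeric(l$c_out)
      }
    }
  })
  structure(list(layers = layers, input_hw = input_hw), class = "cnn_net")
}

# Forward pass. X: (HW, B) single-channel pixel-major input. Returns the
# network output and, if keep_cache, everything backward needs;
# `record_act` stores the activation after that layer (Grad-CAM target).
net_forward <- function(net, X, B, keep_cache = FALSE, record_act = 0L) {
  H <- net$input_hw[1]; W <- net$input_hw[2]
  # fixed input normalisation: intensities in [0,1] -> zero-centred, unit-ish
  A <- (X - 0.5) * 2
  C <- 1L; curH <- H; curW <- W
  act <- NULL; act_hw <- NULL; act_c <- NULL
  cache <- if (keep_cache) vector("list", length(net$layers)) else NULL
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$type == "conv3") {
      g <- conv3_geom(curH, curW, C, B)
      Apad <- matrix(0, g$P, C * B)
      Apad[g$E, ] <- A
      Col <- Apad[g$I]
      dim(Col) <- c(9L * C, g$HW * B)
      Z <- l$W %*% Col + l$b
      A2 <- to_pixel_major(Z, g$HW, l$c_out, B)
      if (keep_cache) cache[[i]] <- list(Col = Col, C_in = C, H = curH, W = curW)
      A <- A2; C <- l$c_out
    } else if (l$type == "conv1") {
      Xc <- to_channel_major(A, curH * curW, C, B)
      Z <- l$W %*% Xc + l$b
      if (keep_cache) cache[[i]] <- list(Xc = Xc, C_in = C, H = curH, W = curW)
      A <- to_pixel_major(Z, curH * curW, l$c_out, B)
      C <- l$c_out
    } else if (l$type == "relu") {
      if (keep_cache) cache[[i]] <- list(mask = A > 0)
      A <- A * (A > 0)
    } else if (l$type == "pool2") {
      pg <- pool2_geom(curH, curW)
      r <- pool2_forward(A, pg)
      if (keep_cache) cache[[i]] <- list(arg = r$arg, pg = pg, C = C,
                                         H = curH, W = curW)
      A <- r$out; curH <- pg$Ho; curW <- pg$Wo
    } else if (l$type == "gap") {
      HW <- curH * curW
      if (keep_cache) cache[[i]] <- list(H = curH, W = curW, C = C, A_in = A)
      A <- matrix(colMeans(A), C, B) # (C, B)
      curH <- 1L; curW <- 1L
    } else if (l$type == "dense") {
      if (keep_cache) cache[[i]] <- list(X = A)
      A <- l$W %*% A + l$b
      C <- l$c_out
    } else stop("unknown layer type ", l$type)
    if (i == record_act) {
      act <- A; act_hw <- c(curH, curW); act_c <- C
    }
  }
  list(out = A, cache = cache, out_hw = c(curH, curW), out_c = C,
       act = act, act_hw = act_hw, act_c = act_c)
}

pool2_geom <- function(H, W) {
  key <- sprintf("p2_%d_%d", H, W)
  if (!is.null(nn_cache[[key]])) return(nn_cache[[key]])
  stopifnot(H %% 2 == 0, W %% 2 == 0)
  Ho <- H %/% 2L; Wo <- W %/% 2L
  yo <- rep(seq_len(Ho), times = Wo); xo <- rep(seq_len(Wo), each = Ho)
  base_y <- 2L * yo - 1L; base_x <- 2L * xo - 1L
  idx <- function(dy, dx) (base_y + dy) + H * (base_x + dx - 1L)
  g <- list(Ho = Ho, Wo = Wo,
            i = list(idx(0L, 0L), idx(1L, 0L), idx(0L, 1L), idx(1L, 1L)))
  nn_cache[[key]] <- g
  g
}

pool2_forward <- function(A, pg) {
  best <- A[pg$i[[1]], , drop = FALSE]
  arg <- matrix(1L, nrow(best), ncol(best))
  for (k in 2:4) {
    Ak <- A[pg$i[[k]], , drop = FALSE]
    sel <- Ak > best
    best[sel] <- Ak[sel]
    arg[sel] <- k
  }
  list(out = best, arg = arg)
}

# Backward pass from dOut (gradient w.r.t. network output, same layout as
# the forward output). Returns per-layer parameter gradients and, if
# `until > 0`, stops early and returns the gradient w.r.t. the output of
# layer `until` (used by Grad-CAM).
net_backward <- function(net, fwd, dOut, B, until = 0L) {
  grads <- vector("list", length(net$layers))
  dA <- dOut
  for (i in rev(seq_along(net$layers))) {
    if (i == until) return(list(grads = grads, dA = dA))
    l <- net$layers[[i]]
    cc <- fwd$cache[[i]]
    if (l$type == "dense") {
      grads[[i]] <- list(dW = dA %*% t(cc$X), db = rowSums(dA))
      dA <- crossprod(l$W, dA)
    } else if (l$type == "gap") {
      HW <- cc$H * cc$W
      # each pixel receives dOut / HW
      dA <- matrix(rep(as.vector(dA), each = HW) / HW, HW, cc$C * B)
    } else if (l$type == "relu") {
      dA <- dA * cc$mask
    } else if (l$type == "pool2") {
      pg <- cc$pg
      dIn <- matrix(0, cc$H * cc$W, ncol(dA))
      for (k in 1:4) {
        dk <- dA * (cc$arg == k)
        dIn[pg$i[[k]], ] <- dIn[pg$i[[k]], ] + dk
      }
      dA <- dIn
    } else if (l$type == "conv1") {
      HW <- cc$H * cc$W
      dZ <- to_channel_major(dA, HW, l$c_out, B)
      grads[[i]] <- list(dW = dZ %*% t(cc$Xc), db = rowSums(dZ))
      if (i > 1) dA <- to_pixel_major(crossprod(l$W, dZ), HW, cc$C_in, B)
    } else if (l$type == "conv3") {
      HW <- cc$H * cc$W
      dZ <- to_channel_major(dA, HW, l$c_out, B)
      grads[[i]] <- list(dW = dZ %*% t(cc$Col), db = rowSums(dZ))
      if (i > 1) {
        # gradient w.r.t. input = same-conv of dZ with flipped kernels
        Wflip <- flip_conv_weights(l$W, l$c_in, l$c_out)
        g <- conv3_geom(cc$H, cc$W, l$c_out, B)
        dOutPix <- to_pixel_major(dZ, HW, l$c_out, B)
        Dpad <- matrix(0, g$P, l$c_out * B)
        Dpad[g$E, ] <- dOutPix
        Col2 <- Dpad[g$I]
        dim(Col2) <- c(9L * l$c_out, HW * B)
        dA <- to_pixel_major(Wflip %*% Col2, HW, cc$C_in, B)
      }
    } else stop("unknown layer type ", l$type)
  }
  list(grads = grads, dA = dA)
}

# W (c_out, 9*c_in) -> Wflip (c_in, 9*c_out) with spatially flipped offsets;
# realised as a cached index permutation.
flip_conv_weights <- function(W, c_in, c_out) {
  key <- sprintf("fw_%d_%d", c_in, c_out)
  idx <- nn_cache[[key]]
  if (is.null(idx)) {
    ci <- rep(seq_len(c_in), times = 9L * c_out)
    kf <- rep(rep(1:9, each = c_in), times = c_out)          # k' in Wf column
    co <- rep(seq_len(c_out), each = 9L * c_in)
    idx <- co + c_out * (((10L - kf) + 9L * (ci - 1L)) - 1L) # index into W
    nn_cache[[key]] <- idx
  }
  Wf <- W[idx]
  dim(Wf) <- c(c_in, 9L * c_out)
  Wf
}

# ---- loss & optimiser -------------------------------------------------------

# Softmax cross-entropy over logits (K, N); labels in 1..K.
softmax_ce <- function(logits, labels) {
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  p <- sweep(e, 2, colSums(e), "/")
  n <- ncol(logits)
  loss <- -mean(log(pmax(p[cbind(labels, seq_len(n))], 1e-12)))
  dlogits <- p
  dlogits[cbind(labels, seq_len(n))] <- dlogits[cbind(labels, seq_len(n))] - 1
  list(loss = loss, dlogits = dlogits / n, probs = p)
}

adam_init <- function(net) {
  lapply(net$layers, function(l)
    if (!is.null(l$W)) list(mW = l$W * 0, vW = l$W * 0,
                            mb = l$b * 0, vb = l$b * 0))
}

adam_step <- function(net, grads, state, t, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    c1 <- 1 - beta1^t; c2 <- 1 - beta2^t
    net$layers[[i]]$W <- net$layers[[i]]$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    net$layers[[i]]$b <- net$layers[[i]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[i]] <- s
  }
  list(net = net, state = state)
}

# ---- architectures ----------------------------------------------------------

#' Stage-1 patch classifier architecture
#'
#' Four 3x3 convolution blocks (8, 16, 32, 32 channels; max pooling after
#' the first two), global average pooling and a 2-class dense head. The last
#' convolution's post-ReLU feature maps (patch/4 resolution) are the
#' Grad-CAM target.
#'
#' @param patch_px input patch side (default 32).
#' @param seed initialisation seed.
#' @return An initialised `cnn_net`.
#' @export
stage1_net <- function(patch_px = 32, seed = 1) {
  init_net(list(layer_conv3(1, 8), layer_relu(), layer_pool2(),
                layer_conv3(8, 16), layer_relu(), layer_pool2(),
                layer_conv3(16, 32), layer_relu(),
                layer_conv3(32, 32), layer_relu(),
                layer_gap(), layer_dense(32, 2)),
           c(patch_px, patch_px), seed)
}

#' Stage-2 segmentation network architecture
#'
#' Three 3x3 convolutions (12 channels each) at full patch resolution
#' followed by a 1x1 convolution to per-pixel background/vesicle logits.
#'
#' @param patch_px input patch side (default 32).
#' @param seed initialisation seed.
#' @return An initialised `cnn_net`.
#' @export
stage2_net <- function(patch_px = 32, seed = 1) {
  init_net(list(layer_conv3(1, 16), layer_relu(),
                layer_conv3(16, 16), layer_relu(),
                layer_conv3(16, 16), layer_relu(),
                layer_conv1(16, 2)),
           c(patch_px, patch_px), seed)
}

# Index of the last conv3+relu pair's relu (Grad-CAM target) in a net.
last_conv_relu_index <- function(net) {
  idx <- 0L
  for (i in seq_along(net$layers))
    if (net$layers[[i]]$type == "relu" &&
        i > 1 && net$layers[[i - 1]]$type == "conv3") idx <- i
  if (idx == 0L) stop("network has no conv3+relu block")
  idx
}

# ---- prediction helpers -----------------------------------------------------

# Classifier class probabilities for patches X (HW, N); chunked to bound the
# index-cache size. Returns N x 2 matrix.
predict_proba <- function(net, X, chunk = 256L) {
  N <- ncol(X)
  out <- matrix(0, N, 2)
  for (s in seq(1L, N, by = chunk)) {
    e <- min(N, s + chunk - 1L)
    Bc <- e - s + 1L
    logits <- net_forward(net, X[, s:e, drop = FALSE], Bc)$out
    m <- apply(logits, 2, max)
    ex <- exp(sweep(logits, 2, m))
    out[s:e, ] <- t(sweep(ex, 2, colSums(ex), "/"))
  }
  out
}

# Per-pixel foreground probability for patches X (HW, N): (HW, N) matrix.
predict_pixel_proba <- function(net, X, chunk = 128L) {
  N <- ncol(X); HW <- nrow(X)
  out <- matrix(0, HW, N)
  for (s in seq(1L, N, by = chunk)) {
    e <- min(N, s + chunk - 1L)
    Bc <- e - s + 1L
    r <- net_forward(net, X[, s:e, drop = FALSE], Bc)
    Z <- to_channel_major(r$out, HW, 2L, Bc) # (2, HW*B)
    p <- 1 / (1 + exp(Z[1, ] - Z[2, ]))      # softmax of 2 classes
    out[, s:e] <- matrix(p, HW, Bc)
  }
  out
}
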