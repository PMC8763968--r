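#' Grad-CAM localization and whole-image scanning
#'
#' Gradient-weighted class activation mapping on the stage-1 patch
#' classifier: per-channel weights are the spatial average of the class
#' score's gradient with respect to the last convolutional feature maps;
#' the localization map is the rectified, weighted sum of those maps,
#' bilinearly upsampled to patch size and max-normalised to [0, 1].
#' [scan_localize()] tiles a whole image with overlapping patches, stitches
#' the maps of vesicle-positive patches, and extracts regions of interest.
#'
#' @name gradcam
NULL

#' Grad-CAM localization map of one patch
#'
#' @param bundle a `model_bundle` with a trained stage 1.
#' @param patch patch pixels: a patch_px x patch_px matrix or a pixel vector.
#' @param class_index class whose evidence is localized (1 = background,
#'   2 = vesicle, the default).
#' @return A `localization_map`: list with `scores` (patch_px x patch_px
#'   matrix in [0, 1]; all zero when the class has no positive evidence) and
#'   `origin` (the (x0, y0) pixel offset of the region, 0-based; `c(0, 0)`
#'   for a bare patch).
#' @export
grad_cam <- function(bundle, patch, class_index = 2L) {
  net <- need_stage(bundle, 1)
  if (!class_index %in% 1:2) stop("class_index out of range (1 or 2)")
  px <- bundle$patch_px
  X <- as.vector(patch)
  if (length(X) != px * px) stop("patch size does not match the model patch_px")
  m <- grad_cam_batch(net, matrix(X, ncol = 1), class_index)[[1]]
  structure(list(scores = m, origin = c(0L, 0L)), class = "localization_map")
}

# Batched Grad-CAM: X (HW, B) -> list of B upsampled, normalised maps.
grad_cam_batch <- function(net, X, class_index = 2L) {
  B <- ncol(X)
  target <- last_conv_relu_index(net)
  fwd <- net_forward(net, X, B, keep_cache = TRUE, record_act = target)
  dOut <- matrix(0, 2, B)
  dOut[class_index, ] <- 1 # gradient of the class score (pre-softmax logit)
  bk <- net_backward(net, fwd, dOut, B, until = target)
  HWc <- prod(fwd$act_hw)
  C <- fwd$act_c
  A <- array(fwd$act, c(HWc, C, B))
  G <- array(bk$dA, c(HWc, C, B))
  px <- net$input_hw[1]
  lapply(seq_len(B), function(b) {
    alpha <- colMeans(G[, , b, drop = FALSE][, , 1, drop = TRUE])
    map <- A[, , b] %*% alpha
    map[map < 0] <- 0
    dim(map) <- fwd$act_hw
    map <- bilinear_resize(map, px, net$input_hw[2])
    mx <- max(map)
    if (mx > 0) map <- map / mx
    map
  })
}

#' Scan an image for vesicle regions of interest
#'
#' Tiles the image with overlapping patches (stride <= patch size), runs the
#' stage-1 classifier on every tile, and stitches the Grad-CAM maps of tiles
#' whose vesicle probability reaches `roi_threshold` into an image-level
#' localization map (overlaps averaged). ROIs are anchored on the stitched
#' map's local maxima: peaks at or above `roi_threshold` (after non-maximum
#' suppression within `suppress_px`) each spawn a patch-sized box. Because
#' the peak set only shrinks as the threshold rises, the ROI count is
#' monotone non-increasing in `roi_threshold`.
#'
#' @param bundle a `model_bundle` with a trained stage 1.
#' @param image grayscale image matrix (values in [0, 1]).
#' @param stride_px scan stride (default half the patch size).
#' @param roi_threshold peak threshold on the stitched map, in (0, 1).
#' @param contrib_threshold tiles with vesicle probability at or above this
#'   contribute their Grad-CAM map to the stitched map (default 0.5). Kept
#'   separate from `roi_threshold` so the stitched map — and therefore the
#'   peak hierarchy — does not change when the ROI threshold is varied.
#' @param suppress_px non-maximum-suppression radius between peaks.
#' @param smooth_sigma Gaussian smoothing of the stitched map before peak
#'   extraction (px; 0 disables). Overlap-averaged maps are lumpy at the
#'   tile scale; smoothing leaves about one peak per vesicle.
#' @param roi_box_px side of the box spawned around each peak (default the
#'   stage-1 patch size).
#' @return List with `rois` (list of `list(x0, y0, width, height, score)`,
#'   0-based pixel bounding boxes), `peaks` (matrix of peak x, y, value),
#'   `map` (the stitched image-level localization map) and `tile_probs`
#'   (per-tile vesicle probabilities).
#' @export
scan_localize <- function(bundle, image, stride_px = NULL, roi_threshold = 0.5,
                          contrib_threshold = 0.5, suppress_px = 8L,
                          smooth_sigma = 3, roi_box_px = NULL) {
  net <- need_stage(bundle, 1)
  px <- bundle$patch_px
  H <- nrow(image); W <- ncol(image)
  if (H < px || W < px) stop("image smaller than the model patch")
  if (is.null(stride_px)) stride_px <- px %/% 2L
  if (stride_px > px) stop("stride_px must not exceed the patch size")

  xs <- tile_starts(W, px, stride_px)
  ys <- tile_starts(H, px, stride_px)
  grid <- expand.grid(x0 = xs, y0 = ys)
  n <- nrow(grid)
  X <- matrix(0, px * px, n)
  for (i in seq_len(n))
    X[, i] <- extract_window(image, grid$x0[i], grid$y0[i], px)
  probs <- predict_proba(net, X)[, 2]

  acc <- matrix(0, H, W); cnt <- matrix(0, H, W)
  hot <- which(probs >= contrib_threshold)
  for (s in if (length(hot)) seq(1, length(hot), by = 64L) else integer(0)) {
    ids <- hot[s:min(length(hot), s + 63L)]
    maps <- grad_cam_batch(net, X[, ids, drop = FALSE], 2L)
    for (k in seq_along(ids)) {
      i <- ids[k]
      rr <- (grid$y0[i] + 1):(grid$y0[i] + px)
      ccn <- (grid$x0[i] + 1):(grid$x0[i] + px)
      # evidence-weighted stitching: a borderline tile contributes a faint
      # map, a confident tile a full-scale one
      acc[rr, ccn] <- acc[rr, ccn] + maps[[k]] * probs[i]
      cnt[rr, ccn] <- cnt[rr, ccn] + 1
    }
  }
  stitched <- acc
  nz <- cnt > 0
  stitched[nz] <- acc[nz] / cnt[nz]
  if (smooth_sigma > 0) stitched <- EBImage::gblur(stitched, sigma = smooth_sigma)

  if (is.null(roi_box_px)) roi_box_px <- px
  pk <- map_peaks(stitched, roi_threshold, suppress_px)
  rois <- peaks_to_rois(pk, roi_box_px, H, W)
  list(rois = rois, peaks = pk, map = stitched, tile_probs = probs)
}

tile_starts <- function(extent, px, stride) {
  s <- seq(0L, extent - px, by = stride)
  if (s[length(s)] != extent - px) s <- c(s, extent - px)
  as.integer(s)
}

# Local maxima of the stitched map at or above thr, greedily thinned by
# non-maximum suppression (a peak within `suppress` px of a stronger kept
# peak is dropped). Returns a matrix with columns x, y (0-based), value.
map_peaks <- function(map, thr, suppress) {
  H <- nrow(map); W <- ncol(map)
  pad <- matrix(-Inf, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- map
  is_max <- map >= thr
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    is_max <- is_max & map >= pad[(2 + dy):(H + 1 + dy), (2 + dx):(W + 1 + dx)]
  }
  w <- which(is_max, arr.ind = TRUE)
  if (!nrow(w)) return(matrix(numeric(0), 0, 3,
                              dimnames = list(NULL, c("x", "y", "value"))))
  v <- map[w]
  ord <- order(v, decreasing = TRUE)
  w <- w[ord, , drop = FALSE]; v <- v[ord]
  keep <- logical(length(v))
  for (i in seq_along(v)) {
    ki <- which(keep)
    if (!length(ki) ||
        all((w[ki, 1] - w[i, 1])^2 + (w[ki, 2] - w[i, 2])^2 > suppress^2))
      keep[i] <- TRUE
  }
  cbind(x = w[keep, 2] - 1, y = w[keep, 1] - 1, value = v[keep])
}

# A clamped box of side box_px centred on each peak.
peaks_to_rois <- function(pk, box_px, H, W) {
  lapply(seq_len(nrow(pk)), function(i) {
    half <- box_px %/% 2L
    x0 <- max(0L, min(W - box_px, as.integer(round(pk[i, "x"])) - half))
    y0 <- max(0L, min(H - box_px, as.integer(round(pk[i, "y"])) - half))
    list(x0 = x0, y0 = y0, width = box_px, height = box_px,
         score = unname(pk[i, "value"]))
  })
}

need_stage <- function(bundle, stage) {
  stopifnot(inherits(bundle, "model_bundle"))
  net <- bundle[[paste0("stage", stage)]]
  if (is.null(net)) stop("model bundle has no trained stage-", stage, " network")
  net
}
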