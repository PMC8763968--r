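#' Vesicle instance segmentation within ROIs
#'
#' Runs the stage-2 segmentation network over each region of interest (tiled
#' with overlapping patches, per-pixel probabilities averaged), thresholds
#' the foreground probability, and converts connected components into
#' vesicle instances with centroid, mask, equivalent diameter and score.
#' Instances found in overlapping ROIs are deduplicated by centroid
#' distance.
#'
#' @param bundle a `model_bundle` with a trained stage 2.
#' @param image grayscale image matrix in [0, 1].
#' @param rois list of ROIs from [scan_localize()] (`list(x0, y0, width,
#'   height)`), or `NULL` to segment the whole image.
#' @param prob_threshold foreground probability threshold (default 0.5).
#' @param min_area_px minimum component area in pixels (default 30; a
#'   nominal 50 nm vesicle at 5 nm/px covers ~78 px and even a 35 nm one —
#'   three SDs below the generator mean — covers ~38 px).
#' @param dedup_px centroid distance below which two instances are the same
#'   vesicle (default 5 px, half a default vesicle diameter).
#' @param stage2_patch_px patch size the stage-2 network expects (taken from
#'   the network input if `NULL`).
#' @return data.frame with one row per instance: `x_px`, `y_px` (0-based
#'   centroid), `area_px`, `diameter_nm`, `score`; the binary component
#'   masks are in attribute `"masks"` (list of `list(offset, mask)`).
#' @export
segment_vesicles <- function(bundle, image, rois, prob_threshold = 0.5,
                             min_area_px = 30L, dedup_px = 5,
                             stage2_patch_px = NULL) {
  net <- need_stage(bundle, 2)
  px <- if (is.null(stage2_patch_px)) net$input_hw[1] else stage2_patch_px
  H <- nrow(image); W <- ncol(image)
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      area_px = numeric(0), diameter_nm = numeric(0),
                      score = numeric(0))
  attr(empty, "masks") <- list()
  if (is.null(rois))
    rois <- list(list(x0 = 0L, y0 = 0L, width = W, height = H))
  if (!length(rois)) return(empty)

  inst <- list()
  for (roi in rois) {
    p <- roi_pixel_proba(net, image, roi, px)
    if (is.null(p)) next
    bin <- p$prob >= prob_threshold
    if (!any(bin)) next
    lab <- EBImage::bwlabel(bin)
    for (l in seq_len(max(lab))) {
      w <- which(lab == l, arr.ind = TRUE)
      if (nrow(w) < min_area_px) next
      cy <- mean(w[, 1]) - 1 + p$y0 # back to 0-based image coordinates
      cx <- mean(w[, 2]) - 1 + p$x0
      sc <- mean(p$prob[lab == l])
      r0 <- range(w[, 1]); c0 <- range(w[, 2])
      m <- lab[r0[1]:r0[2], c0[1]:c0[2], drop = FALSE] == l
      inst[[length(inst) + 1]] <-
        list(x = cx, y = cy, area = nrow(w),
             diameter_nm = 2 * sqrt(nrow(w) / pi) * bundle$nm_per_px,
             score = sc,
             offset = c(p$x0 + c0[1] - 1L, p$y0 + r0[1] - 1L), mask = m)
    }
  }
  if (!length(inst)) return(empty)

  # dedupe across overlapping ROIs: keep the higher-score instance
  ord <- order(vapply(inst, `[[`, numeric(1), "score"), decreasing = TRUE)
  kept <- list()
  for (i in ord) {
    ii <- inst[[i]]
    dup <- any(vapply(kept, function(k)
      (k$x - ii$x)^2 + (k$y - ii$y)^2 < dedup_px^2, logical(1)))
    if (!dup) kept[[length(kept) + 1]] <- ii
  }
  out <- data.frame(x_px = vapply(kept, `[[`, numeric(1), "x"),
                    y_px = vapply(kept, `[[`, numeric(1), "y"),
                    area_px = vapply(kept, `[[`, numeric(1), "area"),
                    diameter_nm = vapply(kept, `[[`, numeric(1), "diameter_nm"),
                    score = vapply(kept, `[[`, numeric(1), "score"))
  attr(out, "masks") <- lapply(kept, function(k) k[c("offset", "mask")])
  out
}

# Average per-pixel foreground probability over an ROI, tiled with stride
# px/2. Returns NULL for ROIs that cannot fit a patch even after expansion.
roi_pixel_proba <- function(net, image, roi, px) {
  H <- nrow(image); W <- ncol(image)
  x0 <- max(0L, as.integer(roi$x0)); y0 <- max(0L, as.integer(roi$y0))
  x1 <- min(W - 1L, as.integer(roi$x0 + roi$width - 1))
  y1 <- min(H - 1L, as.integer(roi$y0 + roi$height - 1))
  # expand to at least one patch
  if (x1 - x0 + 1L < px) {
    x0 <- max(0L, x0 - (px - (x1 - x0 + 1L)) %/% 2L)
    x1 <- min(W - 1L, x0 + px - 1L); x0 <- x1 - px + 1L
  }
  if (y1 - y0 + 1L < px) {
    y0 <- max(0L, y0 - (px - (y1 - y0 + 1L)) %/% 2L)
    y1 <- min(H - 1L, y0 + px - 1L); y0 <- y1 - px + 1L
  }
  if (x0 < 0 || y0 < 0) return(NULL)
  w <- x1 - x0 + 1L; h <- y1 - y0 + 1L
  xs <- tile_starts(w, px, max(1L, px %/% 2L)) + x0
  ys <- tile_starts(h, px, max(1L, px %/% 2L)) + y0
  grid <- expand.grid(tx = xs, ty = ys)
  X <- matrix(0, px * px, nrow(grid))
  for (i in seq_len(nrow(grid)))
    X[, i] <- extract_window(image, grid$tx[i], grid$ty[i], px)
  P <- predict_pixel_proba(net, X)
  acc <- matrix(0, h, w); cnt <- matrix(0, h, w)
  for (i in seq_len(nrow(grid))) {
    rr <- (grid$ty[i] - y0 + 1L):(grid$ty[i] - y0 + px)
    cc <- (grid$tx[i] - x0 + 1L):(grid$tx[i] - x0 + px)
    acc[rr, cc] <- acc[rr, cc] + matrix(P[, i], px, px)
    cnt[rr, cc] <- cnt[rr, cc] + 1
  }
  list(prob = acc / pmax(cnt, 1), x0 = x0, y0 = y0)
}

#' Detect vesicles in a whole image
#'
#' The full two-stage detector: stage-1 scan with Grad-CAM localization
#' ([scan_localize()]) followed by stage-2 instance segmentation within the
#' ROIs ([segment_vesicles()]).
#'
#' @param bundle a `model_bundle` with both stages trained.
#' @param image grayscale image matrix in [0, 1].
#' @param stride_px,roi_threshold passed to [scan_localize()].
#' @param ... passed to [segment_vesicles()].
#' @return The [segment_vesicles()] data.frame, with the scan result in
#'   attribute `"scan"`.
#' @export
detect_vesicles <- function(bundle, image, stride_px = NULL,
                            roi_threshold = 0.5, ...) {
  scan <- scan_localize(bundle, image, stride_px, roi_threshold)
  out <- segment_vesicles(bundle, image, scan$rois, ...)
  attr(out, "scan") <- scan
  out
}
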