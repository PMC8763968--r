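#' Labeled patch datasets from synthetic scenes
#'
#' Builds fixed-size grayscale patch datasets with labels derived from scene
#' ground truth: positives centred (with jitter) on vesicle centres,
#' negatives sampled from vesicle-free windows. In `classify` mode the label
#' is vesicle-present vs background; in `segment` mode each patch carries a
#' per-pixel vesicle mask. A random 20% of the items (stratified by class,
#' so both classes appear in both splits) is assigned to the validation
#' split; the assignment depends on the seed only.
#'
#' @param scenes list of `synthesize_scene()` results (image + truth), or a
#'   single such result.
#' @param patch_px patch side in pixels (must be smaller than the images).
#' @param n_patches total number of patches.
#' @param mode `"classify"` or `"segment"`.
#' @param seed integer seed controlling sampling, jitter and the split.
#' @param pos_fraction fraction of vesicle-positive patches (default 0.5).
#' @param jitter_px positive patches are centred within this many pixels of
#'   a vesicle centre (uniform integer jitter, default 3).
#' @param replace sample vesicle centres with replacement (default `TRUE`;
#'   with `FALSE`, requesting more positives than available vesicles is an
#'   error).
#' @param validation_fraction held-out fraction (default 0.20).
#' @return A `patch_dataset`: list with `patches` (HW x n matrix, pixel
#'   intensities), `labels` (length-n integer, 1 = background, 2 = vesicle)
#'   or `masks` (HW x n 0/1 matrix in segment mode; labels also present),
#'   `split` (character, `"train"`/`"validation"`), `mode`, `patch_px`,
#'   `nm_per_px`, `seed`.
#' @export
make_patch_dataset <- function(scenes, patch_px = 32, n_patches = 2000,
                               mode = c("classify", "segment"), seed = 1,
                               pos_fraction = 0.5, jitter_px = 3,
                               replace = TRUE, validation_fraction = 0.20) {
  mode <- match.arg(mode)
  if (!is.null(scenes$image)) scenes <- list(scenes)
  stopifnot(length(scenes) >= 1, n_patches >= 1)
  for (s in scenes) {
    if (is.null(s$image)) stop("make_patch_dataset: scenes must be rendered")
    if (patch_px >= min(dim(s$image)))
      stop("patch_px must be smaller than the scene images")
  }
  nm_per_px <- scenes[[1]]$truth$nm_per_px

  centers <- do.call(rbind, lapply(seq_along(scenes), function(i) {
    tr <- scenes[[i]]$truth
    if (!tr$vesicle_count) return(NULL)
    cbind(scene = i, x = tr$vesicle_centers[, 1], y = tr$vesicle_centers[, 2],
          r = tr$vesicle_radii_px)
  }))
  n_pos <- round(n_patches * pos_fraction)
  if (n_pos > 0 && is.null(centers))
    stop("positives requested but the scenes contain no vesicles")
  if (!replace && n_pos > NROW(centers))
    stop(sprintf("requested %d positives without replacement but only %d vesicles exist",
                 n_pos, NROW(centers)))
  n_neg <- n_patches - n_pos

  with_seed(seed, {
    half <- patch_px %/% 2
    HW <- patch_px * patch_px
    patches <- matrix(0, HW, n_patches)
    masks <- if (mode == "segment") matrix(0L, HW, n_patches) else NULL
    labels <- integer(n_patches)

    pick <- if (n_pos > 0) sample(NROW(centers), n_pos, replace = replace) else integer(0)
    col <- 0L
    for (i in pick) {
      col <- col + 1L
      sc <- scenes[[centers[i, "scene"]]]
      H <- nrow(sc$image); W <- ncol(sc$image)
      jx <- sample(-jitter_px:jitter_px, 1); jy <- sample(-jitter_px:jitter_px, 1)
      x0 <- clamp_int(round(centers[i, "x"]) - half + jx, 0L, W - patch_px)
      y0 <- clamp_int(round(centers[i, "y"]) - half + jy, 0L, H - patch_px)
      patches[, col] <- extract_window(sc$image, x0, y0, patch_px)
      labels[col] <- 2L
      if (mode == "segment")
        masks[, col] <- window_vesicle_mask(sc$truth, x0, y0, patch_px)
    }
    for (j in seq_len(n_neg)) {
      col <- col + 1L
      repeat {
        si <- sample(length(scenes), 1)
        sc <- scenes[[si]]
        H <- nrow(sc$image); W <- ncol(sc$image)
        x0 <- sample(0:(W - patch_px), 1); y0 <- sample(0:(H - patch_px), 1)
        if (window_is_vesicle_free(sc$truth, x0, y0, patch_px)) break
      }
      patches[, col] <- extract_window(sc$image, x0, y0, patch_px)
      labels[col] <- 1L
    }

    ord <- sample(n_patches) # interleave classes before splitting
    patches <- patches[, ord, drop = FALSE]
    labels <- labels[ord]
    if (!is.null(masks)) masks <- masks[, ord, drop = FALSE]
    # stratified split: 20% of each class held out, so both classes appear
    # in both splits whenever each class has at least 2 items
    split <- rep("train", n_patches)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      n_val_cl <- round(validation_fraction * length(idx))
      if (n_val_cl > 0) split[sample(idx, n_val_cl)] <- "validation"
    }

    structure(list(patches = patches, labels = labels, masks = masks,
                   split = split, mode = mode, patch_px = patch_px,
                   nm_per_px = nm_per_px, seed = seed), class = "patch_dataset")
  })
}

clamp_int <- function(x, lo, hi) as.integer(pmin(hi, pmax(lo, x)))

# Column-major pixel vector of the patch_px window with 0-based top-left
# (x0, y0). Image is indexed [row, col] = [y + 1, x + 1].
extract_window <- function(img, x0, y0, patch_px) {
  as.vector(img[(y0 + 1):(y0 + patch_px), (x0 + 1):(x0 + patch_px)])
}

# Union of vesicle disks intersecting the window, as a 0/1 pixel vector.
window_vesicle_mask <- function(truth, x0, y0, patch_px) {
  m <- matrix(0L, patch_px, patch_px)
  if (truth$vesicle_count) {
    xs <- x0:(x0 + patch_px - 1); ys <- y0:(y0 + patch_px - 1)
    for (i in seq_len(truth$vesicle_count)) {
      vx <- truth$vesicle_centers[i, 1]; vy <- truth$vesicle_centers[i, 2]
      r <- truth$vesicle_radii_px[i]
      if (vx < x0 - r || vx > x0 + patch_px - 1 + r ||
          vy < y0 - r || vy > y0 + patch_px - 1 + r) next
      d2 <- outer((ys - vy)^2, (xs - vx)^2, "+")
      m[d2 <= r^2] <- 1L
    }
  }
  as.vector(m)
}

# TRUE when no vesicle disk touches the window (negatives are entirely
# vesicle-free).
window_is_vesicle_free <- function(truth, x0, y0, patch_px) {
  if (!truth$vesicle_count) return(TRUE)
  vx <- truth$vesicle_centers[, 1]; vy <- truth$vesicle_centers[, 2]
  r <- truth$vesicle_radii_px + 1
  !any(vx >= x0 - r & vx <= x0 + patch_px - 1 + r &
       vy >= y0 - r & vy <= y0 + patch_px - 1 + r)
}

#' @export
print.patch_dataset <- function(x, ...) {
  cat(sprintf("<patch_dataset> %d patches %dx%d px (%s), %d train / %d validation, %d positive\n",
              ncol(x$patches), x$patch_px, x$patch_px, x$mode,
              sum(x$split == "train"), sum(x$split == "validation"),
              sum(x$labels == 2L)))
  invisible(x)
}
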