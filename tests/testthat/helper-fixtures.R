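# Shared fixtures. Expensive objects (trained detector, detection
# experiment) are built once per test run and memoised here; the acceptance
# tests and the unit tests that need a trained model share the same bundle,
# trained at the default study conditions.

.fixtures <- new.env(parent = emptyenv())

get_default_bundle <- function() {
  if (is.null(.fixtures$bundle))
    .fixtures$bundle <- train_default_detector(seed = 1)
  .fixtures$bundle
}

get_count_recovery <- function() {
  if (is.null(.fixtures$count_recovery))
    .fixtures$count_recovery <-
      experiment_count_recovery(get_default_bundle(), seed = 1)
  .fixtures$count_recovery
}

get_morpho_recovery <- function() {
  if (is.null(.fixtures$morpho_recovery))
    .fixtures$morpho_recovery <- experiment_morpho_recovery(seed = 1)
  .fixtures$morpho_recovery
}

# Tiny pipeline configuration: small scene counts and short training, used
# for structural and determinism checks.
tiny_config <- function() {
  pipeline_config(list(
    seed = 7,
    scenes = list(n_per_group = 2, n_train_scenes = 2),
    train = list(n_patches_stage1 = 200, n_patches_stage2 = 160,
                 max_epoch_stage1 = 8, max_epoch_stage2 = 8, patience = 8,
                 lr = 2e-3)))
}

get_tiny_run <- function() {
  if (is.null(.fixtures$tiny_run)) {
    out <- file.path(tempdir(), "tiny_pipeline_run")
    run_pipeline(tiny_config(), out, quiet = TRUE)
    .fixtures$tiny_run <- out
  }
  .fixtures$tiny_run
}

# A small rendered scene reused by patch/detection unit tests.
get_small_scene <- function() {
  if (is.null(.fixtures$small_scene))
    .fixtures$small_scene <-
      synthesize_scene(scene_params(preset = "train_vesicle", seed = 42))
  .fixtures$small_scene
}

# Brute-force O(n^3) convex hull area: a directed edge (i, j) is on the hull
# iff every other point lies on its left; hull vertices ordered by angle.
brute_hull_area <- function(pts) {
  n <- nrow(pts)
  if (n < 3) return(NA_real_)
  on_hull <- logical(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    cr <- (pts[j, 1] - pts[i, 1]) * (pts[, 2] - pts[i, 2]) -
          (pts[j, 2] - pts[i, 2]) * (pts[, 1] - pts[i, 1])
    cr <- cr[-c(i, j)]
    if (all(cr >= 0) || all(cr <= 0)) on_hull[c(i, j)] <- TRUE
  }
  h <- pts[on_hull, , drop = FALSE]
  if (nrow(h) < 3) return(NA_real_)
  ctr <- colMeans(h)
  h <- h[order(atan2(h[, 2] - ctr[2], h[, 1] - ctr[1])), , drop = FALSE]
  a <- polygon_area(h)
  if (a < 1e-12) NA_real_ else a
}

# Brute-force DBSCAN by reachability closure: core points, then connected
# components of the core graph, then border attachment.
brute_dbscan <- function(pts, eps, min_pts) {
  n <- nrow(pts)
  d <- as.matrix(stats::dist(pts))
  nb <- d <= eps
  core <- rowSums(nb) >= min_pts
  lab <- rep(-1L, n)
  cl <- 0L
  for (i in which(core)) {
    if (lab[i] != -1L) next
    cl <- cl + 1L
    comp <- i
    repeat {
      grow <- which(core & lab == -1L &
                      apply(nb[, comp, drop = FALSE], 1, any))
      grow <- setdiff(grow, comp)
      if (!length(grow)) break
      lab[grow] <- cl
      comp <- c(comp, grow)
    }
    lab[comp] <- cl
  }
  for (i in which(!core & lab == -1L)) {
    cand <- which(core & nb[i, ])
    if (length(cand)) lab[i] <- lab[cand[which.min(d[i, cand])]]
  }
  lab
}

# Same-partition test for two clusterings up to label renaming (noise = -1
# must match exactly).
same_clustering <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(a == -1L, b == -1L)) return(FALSE)
  ok <- a != -1L
  if (!any(ok)) return(TRUE)
  ta <- paste(a[ok]); tb <- paste(b[ok])
  length(unique(paste(ta, tb))) == length(unique(ta)) &&
    length(unique(paste(ta, tb))) == length(unique(tb))
}
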