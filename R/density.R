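#' Per-cell vesicle density via clustering and convex-hull area
#'
#' Detected vesicle centroids are grouped with density-based (DBSCAN-style)
#' clustering; the per-cell density is the vesicle count divided by the
#' convex-hull area of the clustered centroids (the smallest convex set
#' containing the vesicles). Cells with enough vesicles for a non-degenerate
#' hull are "detectable".
#'
#' @name density_stats
NULL

#' Density-based clustering of vesicle centroids
#'
#' DBSCAN: a core point has at least `min_pts` neighbours (itself included)
#' within `eps_nm`; clusters are the connected components of core points
#' under eps-reachability. A border (non-core) point joins the cluster of
#' its nearest core point within `eps_nm` — a deterministic variant of the
#' classic order-dependent border rule. Noise points get label -1. Labels
#' are arbitrary up to renaming.
#'
#' @param centroids n x 2 matrix of points (px).
#' @param eps_nm neighbourhood radius in nm (default 200).
#' @param min_pts minimum neighbourhood size for a core point (default 3).
#' @param nm_per_px physical scale of the centroid coordinates.
#' @return Integer vector of n cluster labels (1, 2, ... or -1 for noise).
#' @export
cluster_vesicles <- function(centroids, eps_nm = 200, min_pts = 3, nm_per_px = 5) {
  n <- nrow(centroids)
  if (!n) return(integer(0))
  eps_px <- eps_nm / nm_per_px
  d2 <- outer(centroids[, 1], centroids[, 1], "-")^2 +
        outer(centroids[, 2], centroids[, 2], "-")^2
  nb <- d2 <= eps_px^2
  core <- rowSums(nb) >= min_pts
  labels <- rep(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != -1L) next
    cl <- cl + 1L
    frontier <- i
    labels[i] <- cl
    while (length(frontier)) {
      nxt <- integer(0)
      for (j in frontier) {
        reach <- which(core & nb[j, ] & labels == -1L)
        labels[reach] <- cl
        nxt <- c(nxt, reach)
      }
      frontier <- unique(nxt)
    }
  }
  for (i in which(!core & labels == -1L)) {
    cand <- which(core & nb[i, ])
    if (length(cand)) labels[i] <- labels[cand[which.min(d2[i, cand])]]
  }
  labels
}

#' Per-cell vesicle profile
#'
#' Turns one cell's vesicle instances into count, hull area, density and the
#' detectable flag. Density is count divided by the convex-hull area of the
#' clustered centroids; by default the hull of the largest cluster
#' (`hull = "largest_cluster"`), alternatively of all centroids
#' (`hull = "all_points"`). With fewer than 3 non-collinear hull points the
#' hull is degenerate and density is `NA`.
#'
#' In `largest_cluster` mode both the numerator and the hull are the largest
#' cluster's (count over its own occupied area); `vesicle_count` always
#' reports all instances.
#'
#' @param instances data.frame of detections with columns `x_px`, `y_px`
#'   (see [segment_vesicles()]), or an n x 2 matrix of centroids.
#' @param cell_id,group identifiers copied into the profile.
#' @param min_count detectable threshold: detectable iff count >= min_count
#'   (default 3, the minimum for a non-degenerate hull).
#' @param eps_nm,min_pts clustering parameters, see [cluster_vesicles()].
#' @param nm_per_px physical scale of the centroid coordinates.
#' @param hull `"largest_cluster"` or `"all_points"`.
#' @return One-row data.frame: `cell_id`, `group`, `vesicle_count`,
#'   `hull_area_um2`, `density_per_um2`, `detectable`.
#' @export
cell_profile <- function(instances, cell_id = "cell", group = NA_character_,
                         min_count = 3, eps_nm = 200, min_pts = 3,
                         nm_per_px = 5,
                         hull = c("largest_cluster", "all_points")) {
  hull <- match.arg(hull)
  pts <- if (is.matrix(instances)) instances
         else cbind(instances$x_px, instances$y_px)
  count <- nrow(pts)
  if (is.null(count)) count <- 0L
  hull_area <- NA_real_
  n_hull <- 0L
  if (count >= 3) {
    use <- pts
    if (hull == "largest_cluster") {
      lab <- cluster_vesicles(pts, eps_nm, min_pts, nm_per_px)
      if (any(lab > 0)) {
        big <- as.integer(names(which.max(table(lab[lab > 0]))))
        use <- pts[lab == big, , drop = FALSE]
      }
    }
    n_hull <- nrow(use)
    hull_area <- convex_hull_area(use) * (nm_per_px / 1000)^2
  }
  data.frame(cell_id = cell_id, group = group, vesicle_count = count,
             hull_area_um2 = hull_area,
             density_per_um2 = if (is.na(hull_area)) NA_real_ else n_hull / hull_area,
             detectable = count >= min_count,
             stringsAsFactors = FALSE)
}

#' Group summaries: mean, SEM, n and detectable proportion
#'
#' Data are summarised as means +/- SEM per group. SEM is SD/sqrt(n); for
#' n = 1 the SEM is reported as 0 and the group flagged.
#'
#' @param profiles data.frame of [cell_profile()] rows.
#' @param value column to summarise (default `"density_per_um2"`; `NA`s,
#'   i.e. cells with degenerate hulls, are dropped from the mean/SEM).
#' @return data.frame with one row per group: `group`, `n_cells`,
#'   `n_detectable`, `prop_detectable`, `n_value`, `mean`, `sem`,
#'   `single_cell_group`.
#' @export
summarize_groups <- function(profiles, value = "density_per_um2") {
  do.call(rbind, lapply(split(profiles, profiles$group), function(d) {
    v <- d[[value]]
    v <- v[!is.na(v)]
    n <- length(v)
    data.frame(group = d$group[1],
               n_cells = nrow(d),
               n_detectable = sum(d$detectable),
               prop_detectable = mean(d$detectable),
               n_value = n,
               mean = if (n) mean(v) else NA_real_,
               sem = if (n > 1) stats::sd(v) / sqrt(n) else if (n == 1) 0 else NA_real_,
               single_cell_group = n == 1,
               stringsAsFactors = FALSE)
  }))
}
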