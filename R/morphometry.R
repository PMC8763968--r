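#' Neuron-SGC morphometry
#'
#' Structural measurements of a neuron soma and its SGC sheath, mirroring the
#' manual TEM workflow: the neuron-to-SGC separation profile around the
#' contour, the three largest gap measurements taken at distinct locations,
#' the binary "distant glia" flag, the maximum caliper (Feret) diameter, the
#' traced area, and circularity as the major/minor axis ratio of the fitted
#' second-moment ellipse (1 = circular, > 1 = elliptic).
#'
#' @name morphometry
NULL

#' Neuron-to-SGC gap profile
#'
#' For points uniformly spaced by arc length along the neuron contour, the
#' distance to the nearest point of the SGC inner membrane. This automates
#' the manual caliper measurement between the two membranes.
#'
#' @param neuron n x 2 neuron contour (um).
#' @param sgc_inner m x 2 SGC inner-membrane contour (um).
#' @param n_samples number of arc-length-uniform sample points (default 720,
#'   i.e. 0.5 degree steps on a round cell).
#' @return Numeric vector of `n_samples` nonnegative distances (um), in
#'   contour order, with the sample points as attribute `"points"`.
#' @export
boundary_gap_profile <- function(neuron, sgc_inner, n_samples = 720) {
  neuron <- validate_contour(neuron, check_simple = FALSE, name = "neuron")
  sgc_inner <- validate_contour(sgc_inner, check_simple = FALSE, name = "sgc_inner")
  if (any(!point_in_polygon(neuron[, 1], neuron[, 2], sgc_inner)))
    stop("geometry error: neuron contour is not strictly inside the SGC inner contour")
  pts <- resample_by_arclength(neuron, n_samples)
  d <- dist_to_contour(pts, sgc_inner)
  attr(d, "points") <- pts
  d
}

# Uniform arc-length resampling of a closed polygon.
resample_by_arclength <- function(xy, n) {
  xy2 <- rbind(xy, xy[1, ])
  seg <- sqrt(diff(xy2[, 1])^2 + diff(xy2[, 2])^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  target <- seq(0, total, length.out = n + 1)[-(n + 1)]
  i <- findInterval(target, s, rightmost.closed = TRUE)
  f <- (target - s[i]) / pmax(seg[i], .Machine$double.eps)
  cbind(xy2[i, 1] + f * (xy2[i + 1, 1] - xy2[i, 1]),
        xy2[i, 2] + f * (xy2[i + 1, 2] - xy2[i, 2]))
}

#' The k largest gap measurements at distinct locations
#'
#' Finds local maxima of the (circular) gap profile, suppresses maxima closer
#' than `exclusion_deg` to a larger one (so the k measurements come from
#' distinct gaps when possible), and returns the k largest in descending
#' order. If fewer than k separated maxima exist, the remainder is padded
#' from the global descending order of the profile and the result is flagged
#' with attribute `"padded" = TRUE`.
#'
#' @param profile numeric vector of gap distances around the contour
#'   (circular order).
#' @param k number of measurements (default 3, as in the manual protocol).
#' @param exclusion_deg minimal angular separation between reported gaps.
#' @return k distances, descending; attribute `"padded"` marks padding.
#' @export
top_gaps <- function(profile, k = 3, exclusion_deg = 20) {
  n <- length(profile)
  if (n < k) stop("profile shorter than k")
  excl <- max(1L, ceiling(exclusion_deg / 360 * n))
  ip <- c(2:n, 1); im <- c(n, 1:(n - 1))
  is_max <- profile >= profile[ip] & profile >= profile[im]
  # plateau handling: keep a single representative per run of equal values
  cand <- which(is_max)
  cand <- cand[order(profile[cand], decreasing = TRUE)]
  chosen <- integer(0)
  for (i in cand) {
    if (length(chosen) == k) break
    circ_d <- pmin(abs(i - chosen), n - abs(i - chosen))
    if (!length(chosen) || all(circ_d >= excl)) chosen <- c(chosen, i)
  }
  padded <- FALSE
  vals <- profile[chosen]
  if (length(vals) < k) {
    padded <- TRUE
    rest <- sort(profile, decreasing = TRUE)
    vals <- c(vals, rest)[seq_len(k)]
  }
  out <- sort(vals, decreasing = TRUE)
  attr(out, "padded") <- padded
  out
}

#' Binary distant-glia flag
#'
#' A neuron is scored 1 ("obvious distant glia") when its largest gap
#' measurement reaches the threshold, else 0. The threshold operationalizes
#' the qualitative scoring rule; the decision at exactly the threshold is 1.
#'
#' @param gaps_um gap measurements (um), any length >= 1.
#' @param threshold_um decision threshold (um), default 0.25.
#' @return Integer 0 or 1.
#' @export
classify_gap <- function(gaps_um, threshold_um = 0.25) {
  stopifnot(length(gaps_um) >= 1, threshold_um > 0)
  as.integer(max(gaps_um) >= threshold_um)
}

#' Neuron diameter at the largest point across
#'
#' Maximum caliper (Feret) diameter of the traced contour.
#'
#' @param xy n x 2 contour (um).
#' @return Diameter (um).
#' @export
neuron_diameter <- function(xy) feret_diameter(xy)

#' Circularity as the fitted-ellipse axis ratio
#'
#' Ratio between the major axis (X) and minor axis (Y) of the second-moment
#' ellipse of the enclosed region; 1 for a circle (and any shape with equal
#' principal moments), > 1 for elongated shapes.
#'
#' @param xy n x 2 contour (um).
#' @return Circularity >= 1.
#' @export
circularity <- function(xy) ellipse_axis_ratio(xy)

#' Traced neuron area
#'
#' Shoelace area of the contour, positive for either orientation.
#'
#' @param xy n x 2 contour (um).
#' @return Area (um^2).
#' @export
contour_area <- function(xy) polygon_area(xy)

#' All per-neuron structural measurements
#'
#' Applies the full measurement protocol to one scene truth (or to a pair of
#' traced contours): gap profile, three largest gaps, distant-glia flag,
#' Feret diameter, area and circularity.
#'
#' @param truth a `scene_truth`, or a list with `neuron_contour` and
#'   `sgc_inner_contour` in px plus `nm_per_px`.
#' @param neuron_id identifier copied into the record.
#' @param threshold_um distant-glia flag threshold (um).
#' @param n_samples gap-profile sampling density.
#' @param exclusion_deg angular separation between reported gaps.
#' @return One-row data.frame: `neuron_id`, `gap_flag`, `gap1_um`, `gap2_um`,
#'   `gap3_um`, `diameter_um`, `area_um2`, `circularity`,
#'   `gap_threshold_um`.
#' @export
measure_neuron <- function(truth, neuron_id = "neuron", threshold_um = 0.25,
                           n_samples = 720, exclusion_deg = 20) {
  um <- truth$nm_per_px / 1000
  neuron <- truth$neuron_contour * um
  sgc <- truth$sgc_inner_contour * um
  prof <- boundary_gap_profile(neuron, sgc, n_samples = n_samples)
  gaps <- top_gaps(prof, k = 3, exclusion_deg = exclusion_deg)
  data.frame(neuron_id = neuron_id,
             gap_flag = classify_gap(gaps, threshold_um),
             gap1_um = round(gaps[1], 3),
             gap2_um = round(gaps[2], 3),
             gap3_um = round(gaps[3], 3),
             diameter_um = neuron_diameter(neuron),
             area_um2 = contour_area(neuron),
             circularity = circularity(neuron),
             gap_threshold_um = threshold_um,
             stringsAsFactors = FALSE)
}

#' Morphometry table for a set of scenes
#'
#' @param truths list of `scene_truth` objects.
#' @param ids neuron identifiers (default sequential).
#' @param ... passed to [measure_neuron()].
#' @return data.frame with one row per neuron.
#' @export
morphometry_table <- function(truths, ids = NULL, ...) {
  if (is.null(ids)) ids <- sprintf("neuron_%03d", seq_along(truths))
  do.call(rbind, Map(function(tr, id) measure_neuron(tr, id, ...), truths, ids))
}
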