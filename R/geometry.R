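#' Polygon and point-set geometry primitives
#'
#' Low-level geometry used throughout the package: shoelace areas, polygon
#' second moments (for the fitted-ellipse axis ratio), Feret diameters,
#' point-in-polygon tests, point-to-contour distances and convex-hull areas.
#' Polygons are n x 2 matrices with columns (x, y); the last vertex must not
#' repeat the first (closure is implicit). Units are whatever the caller
#' supplies; conversions to physical units happen at the module surfaces.
#'
#' @name geometry
#' @keywords internal
NULL

#' Validate a polygon contour
#'
#' Checks the basic contour invariants: at least 3 vertices, finite
#' coordinates, non-zero signed area and (optionally) simplicity, i.e. no
#' pair of non-adjacent edges intersects.
#'
#' @param xy n x 2 numeric matrix of vertices, implicitly closed.
#' @param check_simple test for self-intersection (O(n^2); skipped by default
#'   for contours above 2000 vertices where generation guarantees simplicity).
#' @param name label used in error messages.
#' @return `xy`, invisibly, with a dropped duplicate closing vertex if present.
#' @export
validate_contour <- function(xy, check_simple = nrow(xy) <= 2000, name = "contour") {
  if (!is.matrix(xy) || ncol(xy) != 2 || !is.numeric(xy))
    stop(name, ": vertices must be a numeric n x 2 matrix")
  if (nrow(xy) >= 2 && all(xy[1, ] == xy[nrow(xy), ]))
    xy <- xy[-nrow(xy), , drop = FALSE]
  if (nrow(xy) < 3) stop(name, ": a contour needs at least 3 vertices")
  if (!all(is.finite(xy))) stop(name, ": non-finite vertex coordinates")
  if (check_simple && !polygon_is_simple(xy))
    stop(name, ": contour is self-intersecting")
  if (abs(polygon_signed_area(xy)) < .Machine$double.eps * max(abs(xy), 1)^2)
    stop(name, ": degenerate contour (zero area)")
  invisible(xy)
}

#' @rdname geometry
#' @param xy n x 2 vertex matrix.
#' @export
polygon_signed_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Shoelace area of a simple polygon
#'
#' @param xy n x 2 vertex matrix (implicitly closed).
#' @return Positive area in squared input units, independent of orientation.
#' @export
polygon_area <- function(xy) abs(polygon_signed_area(xy))

#' @rdname geometry
#' @export
polygon_centroid <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Second area moments of a polygon region
#'
#' Exact centered second moments (covariance of the uniform distribution over
#' the enclosed region), from the standard polygon moment integrals.
#'
#' @param xy n x 2 vertex matrix.
#' @return List with `area`, `centroid`, and 2 x 2 covariance matrix `cov`.
#' @export
polygon_second_moments <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  # raw moments about the origin of integral x^2, y^2, xy over the region
  sxx <- sum((x^2 + x * xn + xn^2) * cr) / 12
  syy <- sum((y^2 + y * yn + yn^2) * cr) / 12
  sxy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  covm <- matrix(c(sxx / a - cx^2, sxy / a - cx * cy,
                   sxy / a - cx * cy, syy / a - cy^2), 2, 2)
  list(area = abs(a), centroid = c(cx, cy), cov = covm)
}

#' Major/minor axis ratio of the second-moment ellipse
#'
#' The ellipse with the same second moments as the region has semi-axes
#' `2 * sqrt(lambda)` for the covariance eigenvalues `lambda`; the returned
#' ratio is major/minor, i.e. >= 1 with 1 for a circle (and for any region
#' with equal principal moments, such as a square).
#'
#' @param xy n x 2 vertex matrix.
#' @return Axis ratio >= 1.
#' @export
ellipse_axis_ratio <- function(xy) {
  ev <- eigen(polygon_second_moments(xy)$cov, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= 0) stop("degenerate region: zero minor second moment")
  sqrt(ev[1] / ev[2])
}

#' Maximum caliper (Feret) diameter of a point set or contour
#'
#' Computed as the maximal pairwise distance between convex-hull vertices.
#'
#' @param xy n x 2 matrix of points.
#' @return Feret diameter in input units.
#' @export
feret_diameter <- function(xy) {
  h <- xy[grDevices::chull(xy), , drop = FALSE]
  if (nrow(h) == 1) return(0)
  d2 <- outer(h[, 1], h[, 1], "-")^2 + outer(h[, 2], h[, 2], "-")^2
  sqrt(max(d2))
}

#' Even-odd point-in-polygon test
#'
#' @param px,py coordinates of query points (equal-length vectors).
#' @param xy n x 2 polygon vertex matrix.
#' @return Logical vector; boundary points are implementation-defined
#'   (half-open crossing rule).
#' @export
point_in_polygon <- function(px, py, xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  inside <- logical(length(px))
  for (i in seq_along(x)) {
    crosses <- (y[i] > py) != (yn[i] > py)
    if (any(crosses)) {
      xin <- x[i] + (py[crosses] - y[i]) / (yn[i] - y[i]) * (xn[i] - x[i])
      inside[crosses] <- xor(inside[crosses], px[crosses] < xin)
    }
  }
  inside
}

#' Minimum distance from points to a closed polyline
#'
#' For each query point, the Euclidean distance to the nearest point on any
#' edge of the (implicitly closed) contour.
#'
#' @param pts m x 2 matrix of query points.
#' @param xy n x 2 contour vertex matrix.
#' @return Numeric vector of m nonnegative distances.
#' @export
dist_to_contour <- function(pts, xy) {
  ax <- xy[, 1]; ay <- xy[, 2]
  bx <- c(ax[-1], ax[1]); by <- c(ay[-1], ay[1])
  ex <- bx - ax; ey <- by - ay
  el2 <- ex^2 + ey^2
  el2[el2 == 0] <- 1 # zero-length edges degrade to point distance
  px <- pts[, 1]; py <- pts[, 2]
  best <- rep(Inf, nrow(pts))
  # loop over edges, vectorised over points: n_edges x n_points stays in cache
  for (i in seq_along(ax)) {
    t <- ((px - ax[i]) * ex[i] + (py - ay[i]) * ey[i]) / el2[i]
    t <- pmin(1, pmax(0, t))
    dx <- px - (ax[i] + t * ex[i]); dy <- py - (ay[i] + t * ey[i])
    best <- pmin(best, dx * dx + dy * dy)
  }
  sqrt(best)
}

#' Convex hull area of a planar point set
#'
#' Area of the smallest convex set containing all points. Fewer than three
#' points, or a collinear set, is a degenerate hull and returns `NA_real_`
#' rather than raising: callers mark the corresponding density undefined.
#'
#' @param pts m x 2 matrix of points.
#' @return Hull area in squared input units, or `NA_real_` if degenerate.
#' @export
convex_hull_area <- function(pts) {
  pts <- unique(pts[stats::complete.cases(pts), , drop = FALSE])
  if (nrow(pts) < 3) return(NA_real_)
  h <- grDevices::chull(pts)
  if (length(h) < 3) return(NA_real_)
  a <- polygon_area(pts[h, , drop = FALSE])
  if (a <= .Machine$double.eps * max(abs(pts), 1)^2) return(NA_real_)
  a
}

#' Regular polygonization of an ellipse
#'
#' @param a,b semi-axes; @param center length-2 center; @param angle rotation
#'   (radians); @param n vertex count.
#' @param a,b,center,angle,n see description.
#' @return n x 2 vertex matrix, counter-clockwise.
#' @export
ellipse_polygon <- function(a, b, center = c(0, 0), angle = 0, n = 360) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- a * cos(t); y <- b * sin(t)
  cbind(center[1] + x * cos(angle) - y * sin(angle),
        center[2] + x * sin(angle) + y * cos(angle))
}

# Segment-intersection based simplicity test; adjacent edges share a vertex
# and are excluded.
polygon_is_simple <- function(xy) {
  n <- nrow(xy)
  a <- xy; b <- xy[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2)) {
    js <- (i + 2):n
    if (i == 1) js <- js[js != n]
    if (!length(js)) next
    if (any(segments_intersect(a[i, 1], a[i, 2], b[i, 1], b[i, 2],
                               a[js, 1], a[js, 2], b[js, 1], b[js, 2])))
      return(FALSE)
  }
  TRUE
}

segments_intersect <- function(x1, y1, x2, y2, x3, y3, x4, y4) {
  d1 <- (x2 - x1) * (y3 - y1) - (y2 - y1) * (x3 - x1)
  d2 <- (x2 - x1) * (y4 - y1) - (y2 - y1) * (x4 - x1)
  d3 <- (x4 - x3) * (y1 - y3) - (y4 - y3) * (x1 - x3)
  d4 <- (x4 - x3) * (y2 - y3) - (y4 - y3) * (x2 - x3)
  (d1 * d2 < 0) & (d3 * d4 < 0)
}
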