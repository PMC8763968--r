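#' Synthesize a TEM-like scene with ground truth
#'
#' Renders a grayscale field containing a neuron soma, its enveloping SGC
#' sheath, and vesicle profiles in the SGC cytoplasm, and returns the exact
#' geometry used for rendering as a [scene_truth] object. The construction is
#' fully deterministic in `params$seed`: identical parameters and seed give
#' bit-identical images and truth.
#'
#' Geometry: the neuron contour is an ellipse (optionally with a small
#' low-order radial wobble). The SGC inner membrane is the neuron contour
#' displaced along its outward normals by the angular gap function
#' ([gap_function_um]); the SGC outer membrane adds the sheath thickness.
#' Vesicle centres are a homogeneous Poisson process over the SGC cytoplasm
#' (clipped to the canvas for partial fields); diameters are normal
#' (mean/SD from the parameters) truncated at three SDs.
#'
#' Rendering: membranes are dark curves, compartments have distinct mean
#' intensities with a smooth large-scale texture, vesicles are dark rings
#' (membrane) with a lighter lumen, and the field carries an illumination
#' gradient plus additive Gaussian noise. Intensities live in [0, 1].
#'
#' @param params a [scene_params] object.
#' @param render if `FALSE`, skip rasterization and return only the truth
#'   (fast path for statistical experiments over many scenes).
#' @return List with `image` (H x W matrix in [0,1] with attribute
#'   `nm_per_px`, or `NULL` when `render = FALSE`) and `truth`
#'   (a `scene_truth`).
#' @export
synthesize_scene <- function(params, render = TRUE) {
  stopifnot(inherits(params, "scene_params"))
  with_seed(params$seed, synthesize_scene_impl(params, render))
}

synthesize_scene_impl <- function(p, render) {
  H <- p$image_size_px[1]; W <- p$image_size_px[2]
  px_um <- p$nm_per_px / 1000
  n_theta <- 4320L
  theta <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]

  # --- contours in um, soma frame -------------------------------------------
  ang <- p$soma_angle_deg * pi / 180
  a <- p$soma_axes_um[1]; b <- p$soma_axes_um[2]
  th0 <- theta - ang # angle in the ellipse's own frame
  r_ell <- a * b / sqrt((b * cos(th0))^2 + (a * sin(th0))^2)
  wob_phase <- stats::runif(1, 0, 2 * pi)
  r_n <- r_ell * (1 + p$soma_wobble_amp * cos(p$soma_wobble_harmonic * th0 + wob_phase))
  cx <- p$center_um[1]; cy <- p$center_um[2]
  Px <- cx + r_n * cos(theta); Py <- cy + r_n * sin(theta)
  nrm <- outward_normals(Px, Py)
  g <- gap_function_um(theta, p)
  Qx <- Px + g * nrm[, 1]; Qy <- Py + g * nrm[, 2]
  Sx <- Px + (g + p$sheath_thickness_um) * nrm[, 1]
  Sy <- Py + (g + p$sheath_thickness_um) * nrm[, 2]

  # star-shaped radial lookups about the soma centre, on a uniform angle grid
  lut_theta <- theta
  r_si <- radial_lookup(Qx - cx, Qy - cy, lut_theta)
  r_so <- radial_lookup(Sx - cx, Sy - cy, lut_theta)

  # --- cytoplasm area (Poisson mean) ----------------------------------------
  if (p$field_of_view == "whole_cell") {
    ring_area <- ring_area_polygon(Qx, Qy, Sx, Sy)
    clip <- NULL
  } else {
    clip <- c(0, (W - 1) * px_um, 0, (H - 1) * px_um) # x0, x1, y0, y1
    ring_area <- ring_area_clipped(cx, cy, lut_theta, r_si, r_so, clip)
  }

  # --- vesicles --------------------------------------------------------------
  lambda <- p$vesicle_density_per_um2 * ring_area
  n_ves <- stats::rpois(1, lambda)
  ves <- place_in_ring(n_ves, cx, cy, lut_theta, r_si, r_so, clip)
  d_nm <- truncated_normal(n_ves, p$vesicle_diameter_nm, p$vesicle_diameter_sd_nm)
  r_px <- d_nm / 2 / p$nm_per_px

  to_px <- function(x, y) cbind(x / px_um, y / px_um) # 0-based (x=col, y=row)
  sub <- seq(1L, n_theta, by = 3L) # 1440-vertex truth polygons
  centers_px <- if (n_ves) to_px(ves[, 1], ves[, 2]) else matrix(numeric(0), 0, 2)
  masks <- vesicle_masks(centers_px, r_px, H, W)

  truth <- structure(list(
    neuron_contour = to_px(Px, Py)[sub, , drop = FALSE],
    sgc_inner_contour = to_px(Qx, Qy)[sub, , drop = FALSE],
    sgc_outer_contour = to_px(Sx, Sy)[sub, , drop = FALSE],
    gap_sectors = p$gap_spec,
    vesicle_centers = centers_px,
    vesicle_radii_px = r_px,
    vesicle_masks = masks,
    vesicle_count = n_ves,
    cytoplasm_area_um2 = ring_area,
    nm_per_px = p$nm_per_px,
    image_size_px = c(H, W),
    center_px = c(cx, cy) / px_um,
    params = p), class = "scene_truth")

  img <- if (render)
    render_scene(p, H, W, px_um, cx, cy, lut_theta, r_n, r_si, r_so,
                 centers_px, r_px)
  else NULL
  list(image = img, truth = truth)
}

# Unit outward normals of a closed CCW curve from central differences.
outward_normals <- function(x, y) {
  n <- length(x)
  ip <- c(2:n, 1); im <- c(n, 1:(n - 1))
  tx <- x[ip] - x[im]; ty <- y[ip] - y[im]
  len <- sqrt(tx^2 + ty^2)
  cbind(ty, -tx) / len
}

# Interpolate the polar radius of a star-shaped closed curve onto `ang`.
radial_lookup <- function(dx, dy, ang) {
  phi <- atan2(dy, dx) %% (2 * pi)
  rho <- sqrt(dx^2 + dy^2)
  o <- order(phi)
  phi <- phi[o]; rho <- rho[o]
  phi <- c(phi[length(phi)] - 2 * pi, phi, phi[1] + 2 * pi)
  rho <- c(rho[length(rho)], rho, rho[1])
  stats::approx(phi, rho, xout = ang, rule = 2)$y
}

# Exact ring area between two closed polygons (outer minus inner), um^2.
ring_area_polygon <- function(ix, iy, ox, oy) {
  polygon_area(cbind(ox, oy)) - polygon_area(cbind(ix, iy))
}

# Ring area clipped to the canvas rectangle: Sutherland-Hodgman clipping of
# the outer and inner contours against the rectangle, areas subtracted.
ring_area_clipped <- function(cx, cy, ang, r_si, r_so, clip) {
  inner <- cbind(cx + r_si * cos(ang), cy + r_si * sin(ang))
  outer <- cbind(cx + r_so * cos(ang), cy + r_so * sin(ang))
  clip_area <- function(poly) {
    p <- clip_polygon_rect(poly, clip)
    if (is.null(p) || nrow(p) < 3) 0 else polygon_area(p)
  }
  clip_area(outer) - clip_area(inner)
}

# Clip a simple polygon to an axis-aligned rectangle c(x0, x1, y0, y1).
clip_polygon_rect <- function(poly, rect) {
  halfplanes <- list(function(p) p[, 1] >= rect[1],
                     function(p) p[, 1] <= rect[2],
                     function(p) p[, 2] >= rect[3],
                     function(p) p[, 2] <= rect[4])
  cross_at <- list(function(a, b) { t <- (rect[1] - a[1]) / (b[1] - a[1]); a + t * (b - a) },
                   function(a, b) { t <- (rect[2] - a[1]) / (b[1] - a[1]); a + t * (b - a) },
                   function(a, b) { t <- (rect[3] - a[2]) / (b[2] - a[2]); a + t * (b - a) },
                   function(a, b) { t <- (rect[4] - a[2]) / (b[2] - a[2]); a + t * (b - a) })
  for (k in 1:4) {
    if (is.null(poly) || nrow(poly) < 3) return(NULL)
    keep <- halfplanes[[k]](poly)
    if (all(keep)) next
    out <- vector("list", 2L * nrow(poly))
    m <- 0L
    n <- nrow(poly)
    prev <- n
    for (i in seq_len(n)) {
      a <- poly[prev, ]; b <- poly[i, ]
      ka <- keep[prev]; kb <- keep[i]
      if (kb) {
        if (!ka) { m <- m + 1L; out[[m]] <- cross_at[[k]](a, b) }
        m <- m + 1L; out[[m]] <- b
      } else if (ka) {
        m <- m + 1L; out[[m]] <- cross_at[[k]](a, b)
      }
      prev <- i
    }
    poly <- if (m) do.call(rbind, out[seq_len(m)]) else NULL
  }
  poly
}

# Uniform points in the cytoplasm ring (optionally canvas-clipped), rejection
# sampled in the bounding box.
place_in_ring <- function(n, cx, cy, ang, r_si, r_so, clip) {
  if (n == 0) return(matrix(numeric(0), 0, 2))
  rmax <- max(r_so)
  bb <- c(cx - rmax, cx + rmax, cy - rmax, cy + rmax)
  if (!is.null(clip))
    bb <- c(max(bb[1], clip[1]), min(bb[2], clip[2]),
            max(bb[3], clip[3]), min(bb[4], clip[4]))
  out <- matrix(numeric(0), 0, 2)
  while (nrow(out) < n) {
    m <- max(200L, 4L * (n - nrow(out)))
    x <- stats::runif(m, bb[1], bb[2]); y <- stats::runif(m, bb[3], bb[4])
    th <- atan2(y - cy, x - cx) %% (2 * pi)
    r <- sqrt((x - cx)^2 + (y - cy)^2)
    ri <- stats::approx(ang, r_si, xout = th, rule = 2)$y
    ro <- stats::approx(ang, r_so, xout = th, rule = 2)$y
    keep <- r >= ri & r <= ro
    out <- rbind(out, cbind(x[keep], y[keep]))
  }
  out[seq_len(n), , drop = FALSE]
}

truncated_normal <- function(n, mean, sd, k = 3) {
  if (n == 0) return(numeric(0))
  x <- stats::rnorm(n, mean, sd)
  bad <- abs(x - mean) > k * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- abs(x - mean) > k * sd
  }
  x
}

# Binary disk masks, one per vesicle, clipped to the canvas. Each mask is a
# small logical matrix plus its 0-based (x0, y0) offset.
vesicle_masks <- function(centers_px, r_px, H, W) {
  n <- nrow(centers_px)
  if (!n) return(list())
  lapply(seq_len(n), function(i) {
    cxp <- centers_px[i, 1]; cyp <- centers_px[i, 2]; r <- r_px[i]
    x0 <- max(0L, floor(cxp - r - 1)); x1 <- min(W - 1L, ceiling(cxp + r + 1))
    y0 <- max(0L, floor(cyp - r - 1)); y1 <- min(H - 1L, ceiling(cyp + r + 1))
    xs <- x0:x1; ys <- y0:y1
    d2 <- outer((ys - cyp)^2, (xs - cxp)^2, "+")
    list(offset = c(x0, y0), mask = d2 <= r^2)
  })
}

# --- rendering ---------------------------------------------------------------

render_scene <- function(p, H, W, px_um, cx, cy, ang, r_n, r_si, r_so,
                         centers_px, r_px) {
  xs <- (0:(W - 1)) * px_um; ys <- (0:(H - 1)) * px_um
  dx <- matrix(rep(xs - cx, each = H), H, W)
  dy <- matrix(rep(ys - cy, times = W), H, W)
  th <- atan2(dy, dx) %% (2 * pi)
  r <- sqrt(dx^2 + dy^2)
  Rn <- matrix(stats::approx(ang, r_n, xout = as.vector(th), rule = 2)$y, H, W)
  Ri <- matrix(stats::approx(ang, r_si, xout = as.vector(th), rule = 2)$y, H, W)
  Ro <- matrix(stats::approx(ang, r_so, xout = as.vector(th), rule = 2)$y, H, W)

  mem_half <- max(0.75, 8 / p$nm_per_px) * px_um # >= 0.75 px, ~8 nm membranes
  img <- matrix(0.75, H, W)                       # surrounding tissue
  img[r < Ro] <- 0.50                             # SGC cytoplasm
  img[r < Ri] <- 0.85                             # extracellular gap space
  img[r < Rn] <- 0.55                             # neuron interior
  img[abs(r - Rn) <= mem_half] <- 0.15            # neuron membrane
  img[abs(r - Ri) <= mem_half] <- 0.15            # SGC inner membrane
  img[abs(r - Ro) <= mem_half] <- 0.20            # SGC outer membrane

  img <- img + smooth_texture(H, W, amp = 0.04, scale_px = 16L)
  img <- render_vesicles(img, centers_px, r_px, p$nm_per_px)
  img <- img + illumination_gradient(H, W, amp = 0.05)
  if (p$noise_sd > 0) img <- img + matrix(stats::rnorm(H * W, 0, p$noise_sd), H, W)
  img <- pmin(pmax(img, 0), 1)
  attr(img, "nm_per_px") <- p$nm_per_px
  img
}

# Smooth large-scale intensity texture: coarse Gaussian grid, bilinearly
# upsampled to the canvas.
smooth_texture <- function(H, W, amp, scale_px) {
  h <- max(2L, ceiling(H / scale_px)) + 1L
  w <- max(2L, ceiling(W / scale_px)) + 1L
  coarse <- matrix(stats::rnorm(h * w, 0, 1), h, w)
  bilinear_resize(coarse, H, W) * amp
}

illumination_gradient <- function(H, W, amp) {
  gx <- stats::runif(1, -1, 1) * amp; gy <- stats::runif(1, -1, 1) * amp
  outer((seq_len(H) - 1) / max(1, H - 1) - 0.5, rep(1, W)) * gy +
    outer(rep(1, H), (seq_len(W) - 1) / max(1, W - 1) - 0.5) * gx
}

# Dark membrane ring with a lighter lumen, drawn with soft (Gaussian) edges
# in a local window per vesicle.
render_vesicles <- function(img, centers_px, r_px, nm_per_px) {
  n <- nrow(centers_px)
  if (!n) return(img)
  H <- nrow(img); W <- ncol(img)
  ring_sigma <- max(0.7, 4 / nm_per_px) # ~8 nm membrane
  for (i in seq_len(n)) {
    cxp <- centers_px[i, 1]; cyp <- centers_px[i, 2]; r <- r_px[i]
    pad <- ceiling(r + 3 * ring_sigma)
    x0 <- max(0L, floor(cxp - pad)); x1 <- min(W - 1L, ceiling(cxp + pad))
    y0 <- max(0L, floor(cyp - pad)); y1 <- min(H - 1L, ceiling(cyp + pad))
    if (x0 > x1 || y0 > y1) next
    xs <- x0:x1; ys <- y0:y1
    d <- sqrt(outer((ys - cyp)^2, (xs - cxp)^2, "+"))
    win <- img[ys + 1L, xs + 1L, drop = FALSE]
    lumen <- 1 / (1 + exp((d - (r - ring_sigma)) / (0.5 * ring_sigma)))
    win <- win + lumen * (0.62 - win)                 # lumen slightly bright
    ring <- exp(-((d - r) / ring_sigma)^2)
    win <- win + ring * (0.18 - win)                  # dark membrane ring
    img[ys + 1L, xs + 1L] <- win
  }
  img
}

#' Bilinear resize of a numeric matrix
#'
#' Used for texture upsampling and Grad-CAM map upsampling; corners of the
#' source and target grids are aligned.
#'
#' @param m numeric matrix; @param H,W target dimensions.
#' @param m,H,W see description.
#' @return H x W numeric matrix.
#' @export
bilinear_resize <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  if (h == H && w == W) return(m)
  ry <- if (H == 1) rep(1, 1) else seq(1, h, length.out = H)
  rx <- if (W == 1) rep(1, 1) else seq(1, w, length.out = W)
  y0 <- pmin(floor(ry), h - 1L); x0 <- pmin(floor(rx), w - 1L)
  if (h == 1) y0 <- rep(1, H)
  if (w == 1) x0 <- rep(1, W)
  fy <- ry - y0; fx <- rx - x0
  y1 <- pmin(y0 + 1, h); x1 <- pmin(x0 + 1, w)
  m00 <- m[y0, x0, drop = FALSE]; m01 <- m[y0, x1, drop = FALSE]
  m10 <- m[y1, x0, drop = FALSE]; m11 <- m[y1, x1, drop = FALSE]
  wy <- matrix(fy, H, W); wx <- matrix(fx, H, W, byrow = TRUE)
  m00 * (1 - wy) * (1 - wx) + m01 * (1 - wy) * wx +
    m10 * wy * (1 - wx) + m11 * wy * wx
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %d x %d px at %.3g nm/px, %d vesicles, cytoplasm %.3g um^2\n",
              x$image_size_px[1], x$image_size_px[2], x$nm_per_px,
              x$vesicle_count, x$cytoplasm_area_um2))
  if (length(x$gap_sectors))
    cat(sprintf("  gap sectors: %s\n",
                paste(vapply(x$gap_sectors, function(s)
                  sprintf("%.2f um @ %.0f deg", s$depth_um, s$center_deg),
                  character(1)), collapse = ", ")))
  invisible(x)
}
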