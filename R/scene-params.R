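#' Parameters of a synthetic TEM scene
#'
#' Builds and validates the parameter set for [synthesize_scene()]. A scene is
#' a grayscale TEM-like field containing a roughly elliptic sensory-neuron
#' soma, the thin satellite-glial-cell (SGC) sheath that envelops it, a
#' neuron-to-sheath separation that is tens of nanometres at baseline but may
#' carry configurable micron-scale gap sectors, and ~50 nm vesicle profiles
#' scattered through the SGC cytoplasm as a Poisson point process.
#'
#' Two families of presets mirror the two magnifications at which such
#' material is examined: whole-cell fields for morphometry (`"wt_morpho"`,
#' `"ko_morpho"`; 20 nm/px, the full soma in frame) and high-magnification
#' partial fields of the sheath for vesicle work (`"wt_vesicle"`,
#' `"ko_vesicle"`, `"train_vesicle"`; 5 nm/px, soma centre outside the frame
#' so the cytoplasm crosses it as a band). The KO-like condition differs from
#' WT-like by 2-4 injected gap sectors of 0.5-2 um depth (whole-cell fields)
#' and a doubled vesicle density (high-mag fields).
#'
#' @param preset optional preset name (see Details); explicit arguments
#'   override preset values.
#' @param image_size_px integer length-2, rows x cols.
#' @param nm_per_px physical pixel size in nanometres.
#' @param center_um soma centre in canvas coordinates (um); default canvas
#'   centre.
#' @param soma_axes_um length-2, major and minor semi-axes of the soma (um).
#' @param soma_angle_deg rotation of the soma major axis.
#' @param soma_wobble_amp,soma_wobble_harmonic low-order radial perturbation
#'   giving the soma a slightly irregular outline; amplitude is relative.
#' @param baseline_gap_nm neuron-to-SGC separation outside gap sectors (nm).
#' @param gap_spec list of gap sectors, each `list(center_deg, extent_deg,
#'   depth_um)`; sectors must not overlap and each depth must satisfy the
#'   recoverability rule `R * extent_rad >= 2.6 * depth` (see vignette).
#' @param sheath_thickness_um SGC cytoplasm thickness (um).
#' @param vesicle_density_per_um2 Poisson intensity of vesicle centres in the
#'   SGC cytoplasm.
#' @param vesicle_diameter_nm,vesicle_diameter_sd_nm mean and SD of the
#'   vesicle diameter distribution (normal, truncated at +/- 3 SD).
#' @param noise_sd additive Gaussian pixel noise SD (intensity units, image
#'   range 0-1).
#' @param field_of_view `"whole_cell"` (entire soma plus sheath and gaps must
#'   fit the canvas) or `"partial"` (high-mag crop; the soma may extend
#'   beyond the frame but the cytoplasm must intersect it).
#' @param seed integer seed; every random element of the scene derives from it.
#' @return A validated `scene_params` object (a list).
#' @export
scene_params <- function(preset = NULL,
                         image_size_px = NULL, nm_per_px = NULL,
                         center_um = NULL, soma_axes_um = NULL,
                         soma_angle_deg = NULL,
                         soma_wobble_amp = NULL, soma_wobble_harmonic = NULL,
                         baseline_gap_nm = NULL, gap_spec = NULL,
                         sheath_thickness_um = NULL,
                         vesicle_density_per_um2 = NULL,
                         vesicle_diameter_nm = NULL, vesicle_diameter_sd_nm = NULL,
                         noise_sd = NULL, field_of_view = NULL, seed = NULL) {
  p <- list(image_size_px = c(512L, 512L), nm_per_px = 5,
            center_um = NULL, soma_axes_um = c(1.9, 1.6), soma_angle_deg = 0,
            soma_wobble_amp = 0.01, soma_wobble_harmonic = 3,
            baseline_gap_nm = 30, gap_spec = list(),
            sheath_thickness_um = 0.5, vesicle_density_per_um2 = 10,
            vesicle_diameter_nm = 50, vesicle_diameter_sd_nm = 5,
            noise_sd = 0.03, field_of_view = "partial", seed = 1L)
  if (!is.null(preset)) p <- shallow_merge(p, scene_preset_values(preset, seed))
  supplied <- list(image_size_px = image_size_px, nm_per_px = nm_per_px,
                   center_um = center_um, soma_axes_um = soma_axes_um,
                   soma_angle_deg = soma_angle_deg,
                   soma_wobble_amp = soma_wobble_amp,
                   soma_wobble_harmonic = soma_wobble_harmonic,
                   baseline_gap_nm = baseline_gap_nm, gap_spec = gap_spec,
                   sheath_thickness_um = sheath_thickness_um,
                   vesicle_density_per_um2 = vesicle_density_per_um2,
                   vesicle_diameter_nm = vesicle_diameter_nm,
                   vesicle_diameter_sd_nm = vesicle_diameter_sd_nm,
                   noise_sd = noise_sd, field_of_view = field_of_view,
                   seed = seed)
  p <- shallow_merge(p, supplied[!vapply(supplied, is.null, logical(1))])
  if (is.null(p$center_um))
    p$center_um <- rev(p$image_size_px) / 2 * p$nm_per_px / 1000
  p$image_size_px <- as.integer(p$image_size_px)
  p$seed <- as.numeric(p$seed)
  class(p) <- "scene_params"
  validate_scene_params(p)
  p
}

# Whole-value (non-recursive) list merge: nested lists such as gap_spec are
# replaced, never merged elementwise.
shallow_merge <- function(x, vals) {
  for (nm in names(vals)) x[[nm]] <- vals[[nm]]
  x
}

# Preset tables. KO-like gap sectors and the per-cell soma size factor are
# drawn from the scene seed itself, so each cell gets its own geometry; the
# size distribution is identical for WT-like and KO-like cells (the
# conditions differ in gaps and vesicle density, not in soma morphology).
scene_preset_values <- function(preset, seed = NULL) {
  seed <- if (is.null(seed)) 1 else as.numeric(seed)
  sf <- with_seed(seed * 881 + 3, {
    c(size = min(1.2, max(0.8, stats::rnorm(1, 1, 0.06))),
      ratio = min(1.12, max(0.88, stats::rnorm(1, 1, 0.04))))
  })
  soma_f <- sf["size"]
  morpho_axes <- c(5, 4 * sf["ratio"]) * soma_f # per-cell size and shape
  switch(preset,
    wt_morpho = list(image_size_px = c(1024L, 1024L), nm_per_px = 20,
                     soma_axes_um = unname(morpho_axes),
                     sheath_thickness_um = 0.5,
                     vesicle_density_per_um2 = 0.5, noise_sd = 0.04,
                     field_of_view = "whole_cell",
                     gap_spec = draw_gap_sectors(seed, n_range = 0:2,
                                                 depth_range = c(0.05, 0.12),
                                                 extent_range = c(30, 50),
                                                 r_min_um = unname(morpho_axes[2])),
                     soma_angle_deg = (seed * 37) %% 180),
    ko_morpho = list(image_size_px = c(1024L, 1024L), nm_per_px = 20,
                     soma_axes_um = unname(morpho_axes),
                     sheath_thickness_um = 0.5,
                     vesicle_density_per_um2 = 0.5, noise_sd = 0.04,
                     field_of_view = "whole_cell",
                     gap_spec = draw_gap_sectors(seed, n_range = 2:4,
                                                 depth_range = c(0.5, 2),
                                                 extent_range = c(60, 90),
                                                 r_min_um = unname(morpho_axes[2])),
                     soma_angle_deg = (seed * 37) %% 180),
    wt_vesicle = list(image_size_px = c(512L, 512L), nm_per_px = 5,
                      center_um = c(-7.8, 1.28), soma_axes_um = c(10, 8.5),
                      soma_angle_deg = 90,
                      sheath_thickness_um = 0.6, vesicle_density_per_um2 = 10,
                      field_of_view = "partial"),
    ko_vesicle = list(image_size_px = c(512L, 512L), nm_per_px = 5,
                      center_um = c(-7.8, 1.28), soma_axes_um = c(10, 8.5),
                      soma_angle_deg = 90,
                      sheath_thickness_um = 0.6, vesicle_density_per_um2 = 20,
                      field_of_view = "partial"),
    train_vesicle = list(image_size_px = c(512L, 512L), nm_per_px = 5,
                         center_um = c(-7.8, 1.28), soma_axes_um = c(10, 8.5),
                         soma_angle_deg = 90,
                         sheath_thickness_um = 0.6,
                         vesicle_density_per_um2 = 25,
                         field_of_view = "partial"),
    stop("unknown scene preset: ", preset)
  )
}

#' Draw non-overlapping gap sectors for a KO-like or WT-like cell
#'
#' Sector count, angular extents, positions and depths are drawn from `seed`
#' alone. Depths are capped by the recoverability rule so the injected depth
#' equals the realised nearest-point gap maximum (see vignette); the cap uses
#' the minor semi-axis as the conservative local radius.
#'
#' @param seed integer; @param n_range candidate sector counts;
#'   @param depth_range depth bounds (um); @param extent_range extent bounds
#'   (degrees); @param r_min_um conservative soma radius for the depth cap.
#' @param seed,n_range,depth_range,extent_range,r_min_um see description.
#' @return List of sectors `list(center_deg, extent_deg, depth_um)`.
#' @export
draw_gap_sectors <- function(seed, n_range = 2:4, depth_range = c(0.5, 2),
                             extent_range = c(60, 90), r_min_um = 4) {
  with_seed(seed * 1009 + 7, {
    k <- if (length(n_range) == 1) n_range else sample(n_range, 1)
    if (k == 0) return(list())
    extents <- stats::runif(k, extent_range[1], extent_range[2])
    gapspace <- 360 - sum(extents) - 15 * k
    while (gapspace < 0 && k > 1) { # shed sectors that cannot fit with spacing
      k <- k - 1
      extents <- extents[seq_len(k)]
      gapspace <- 360 - sum(extents) - 15 * k
    }
    spacing <- 15 + as.vector(stats::rmultinom(1, max(0, round(gapspace)), rep(1, k)))
    start <- stats::runif(1, 0, 360)
    centers <- numeric(k)
    pos <- start
    for (i in seq_len(k)) {
      centers[i] <- (pos + extents[i] / 2) %% 360
      pos <- pos + extents[i] + spacing[i]
    }
    depths <- stats::runif(k, depth_range[1], depth_range[2])
    depths <- pmin(depths, r_min_um * (extents * pi / 180) / 2.6)
    mapply(function(c0, e, d) list(center_deg = c0, extent_deg = e, depth_um = d),
           centers, extents, depths, SIMPLIFY = FALSE)
  })
}

validate_scene_params <- function(p) {
  stopifnot(length(p$image_size_px) == 2, all(p$image_size_px > 0))
  if (p$nm_per_px <= 0) stop("nm_per_px must be strictly positive")
  if (any(p$soma_axes_um <= 0)) stop("soma_axes_um must be strictly positive")
  if (p$soma_axes_um[1] < p$soma_axes_um[2] - 1e-12)
    stop("soma_axes_um must be (major, minor)")
  if (p$baseline_gap_nm < 0) stop("baseline_gap_nm must be nonnegative")
  if (p$sheath_thickness_um <= 0) stop("sheath_thickness_um must be strictly positive")
  if (p$vesicle_density_per_um2 < 0) stop("vesicle_density_per_um2 must be nonnegative")
  if (p$vesicle_diameter_nm <= 0) stop("vesicle_diameter_nm must be strictly positive")
  if (p$noise_sd < 0) stop("noise_sd must be nonnegative")
  if (!p$field_of_view %in% c("whole_cell", "partial"))
    stop("field_of_view must be 'whole_cell' or 'partial'")
  validate_gap_spec(p)
  if (p$field_of_view == "whole_cell") validate_scene_fit(p)
  invisible(p)
}

validate_gap_spec <- function(p) {
  gs <- p$gap_spec
  if (!length(gs)) return(invisible(NULL))
  ival <- t(vapply(gs, function(s) {
    stopifnot(s$extent_deg > 0, s$depth_um >= 0)
    c(s$center_deg - s$extent_deg / 2, s$center_deg + s$extent_deg / 2)
  }, numeric(2)))
  ord <- order(ival[, 1] %% 360)
  iv <- ival[ord, , drop = FALSE] - (ival[ord, 1] %/% 360) * 360
  if (nrow(iv) > 1) {
    for (i in seq_len(nrow(iv) - 1))
      if (iv[i + 1, 1] < iv[i, 2]) stop("gap_spec: angular sectors overlap")
    if (iv[nrow(iv), 2] - 360 > iv[1, 1]) stop("gap_spec: angular sectors overlap")
  }
  r_minor <- p$soma_axes_um[2]
  for (s in gs) {
    lim <- r_minor * (s$extent_deg * pi / 180) / 2.6
    if (s$depth_um > lim + 1e-9)
      stop(sprintf(paste0("gap_spec: depth_um %.3f at center %.0f deg exceeds the ",
                          "recoverable limit %.3f for extent %.0f deg ",
                          "(requires soma_minor * extent_rad >= 2.6 * depth)"),
                   s$depth_um, s$center_deg, lim, s$extent_deg))
  }
  invisible(NULL)
}

validate_scene_fit <- function(p) {
  depth_max <- if (length(p$gap_spec))
    max(vapply(p$gap_spec, `[[`, numeric(1), "depth_um")) else 0
  reach <- p$soma_axes_um[1] * (1 + p$soma_wobble_amp) +
    p$baseline_gap_nm / 1000 + depth_max + p$sheath_thickness_um
  ext_um <- rev(p$image_size_px) * p$nm_per_px / 1000 # (x extent, y extent)
  margin <- 2 * p$nm_per_px / 1000
  room <- c(p$center_um, ext_um - p$center_um) - margin
  if (reach > min(room))
    stop(sprintf(paste0("scene does not fit the canvas: soma major axis + gap + ",
                        "sheath reach %.2f um but only %.2f um of canvas is ",
                        "available from the centre (canvas %.2f x %.2f um)"),
                 reach, min(room), ext_um[1], ext_um[2]))
  invisible(NULL)
}

#' Evaluate a parameter set's angular gap function
#'
#' The separation (um) between the neuron membrane and the SGC inner membrane
#' as a function of angle: the baseline separation everywhere, raised inside
#' each gap sector to its depth via a flat central plateau (40% of the
#' extent) with squared-cosine ramps.
#'
#' @param theta angles (radians, soma frame).
#' @param p a `scene_params` object.
#' @return Gap widths in um, same length as `theta`.
#' @export
gap_function_um <- function(theta, p) {
  g <- rep(p$baseline_gap_nm / 1000, length(theta))
  for (s in p$gap_spec) {
    half <- s$extent_deg / 2 * pi / 180
    d <- abs(((theta - s$center_deg * pi / 180) + pi) %% (2 * pi) - pi)
    f <- numeric(length(theta))
    f[d <= 0.4 * half] <- 1
    ramp <- d > 0.4 * half & d < half
    f[ramp] <- cos(pi / 2 * (d[ramp] - 0.4 * half) / (0.6 * half))^2
    g <- pmax(g, p$baseline_gap_nm / 1000 + (s$depth_um - p$baseline_gap_nm / 1000) * f)
  }
  g
}

# Evaluate/restore the RNG around a seeded block so scene generation never
# perturbs the caller's stream. Derived seeds are folded into the 32-bit
# range set.seed accepts.
with_seed <- function(seed, expr) {
  seed <- as.integer(round(abs(as.numeric(seed))) %% 2147483629)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
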