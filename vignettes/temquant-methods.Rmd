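---
title: "Quantifying neuron-glia ultrastructure and SGC vesicles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neuron-glia ultrastructure and SGC vesicles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`temquant` quantifies two ultrastructural phenotypes of sensory
neuron–satellite glial cell (SGC) units in transmission electron
micrographs: (i) the separation between the neuron's outer membrane and the
enveloping SGC sheath — normally tens of nanometres, pathologically
micron-scale — together with standard soma morphometry (Feret diameter,
traced area, axis-ratio circularity); and (ii) the density of ~50 nm
vesicular profiles in the SGC cytoplasm, detected by a two-stage
convolutional network (a patch classifier with Grad-CAM localization
followed by a per-pixel segmentation network) and summarised per cell as
count over convex-hull area. Raw TEM micrographs of neuron-SGC units are
rarely shared, and hand annotation is the bottleneck even when they are,
so the package includes a first-class synthetic scene generator with
complete ground truth; every downstream stage is developed and tested
against it.

# The synthetic scene generator

A scene is a grayscale field containing a roughly elliptic soma, its thin
glial sheath, and vesicles in the SGC cytoplasm.

**Geometry.** The neuron contour is an ellipse (optionally with a small
low-order radial wobble, default amplitude 1%, harmonic 3, which keeps the
contour convex) rotated by a per-cell angle. The SGC inner membrane is the
neuron contour displaced outward along its normals by an angular gap
function: a baseline separation of 30 nm everywhere — the normal
association is on the order of 20–50 nm — raised inside each configured gap
sector to the sector's depth through a flat central plateau (40% of the
sector extent) with squared-cosine ramps. The SGC outer membrane adds the
sheath thickness along the same normals. All three contours are stored as
1440-vertex polygons in 0-based pixel coordinates.

**Why the plateau, and the recoverability rule.** The gap measurement is
nearest-point distance from neuron contour samples to the SGC inner
contour. A gap deeper than its own half-width cannot be measured at full
depth by any nearest-point metric: the ball of radius `depth` around the
deepest neuron point must be free of SGC membrane. The plateau construction
makes the SGC contour locally an exact normal offset (so the distance at
the deepest point equals the injected depth — offsets of convex curves
realise their offset distance), and parameter validation enforces
`R_minor * extent_rad >= 2.6 * depth`, a sufficient condition derived from
the ramp shape for the sector-edge distance not to undercut the depth. This
is why injected depths are recovered within one pixel in the tests, rather
than by tuning tolerances.

**Vesicles.** Centres are a homogeneous Poisson process over the SGC
cytoplasm (intensity = configured density × cytoplasm area; for
partial-field scenes the area is the canvas-clipped ring area). Diameters
are normal with mean 50 nm and SD 5 nm, truncated at ±3 SD; cytoplasmic
vesicular profiles in such material are described only as roughly 50 nm
across, so the spread is a package choice. Each vesicle renders as a dark membrane ring with a slightly
brighter lumen; its ground-truth mask is the disk of its radius.

**Rendering and noise.** Compartments have distinct mean intensities
(membranes dark), overlaid with a smooth large-scale texture (coarse
Gaussian field, bilinearly upsampled), a linear illumination gradient, and
per-pixel additive Gaussian noise (default SD 0.03 on a 0–1 scale). This
mimics TEM background without imitating any particular instrument; no
electron-optics simulation is attempted.

**Presets.** Two magnifications mirror how such material is examined:
whole-cell fields for morphometry (20 nm/px, 1024² px, soma semi-axes
5 × 4 µm with a per-cell ±6% size and ±4% axis-ratio jitter drawn
identically for both conditions — scaled below the 15–50 µm of real
sensory somata so the cell plus micron-scale gaps fits a desk-scale
canvas) and high-magnification
partial fields for vesicle work (5 nm/px, 512² px, soma semi-axes
10 × 8.5 µm — a realistic soma — with the centre far outside the frame, so
the cytoplasm crosses the 2.6 µm field as a gently curved band ~0.6 µm
thick, as it does at high magnification on a real cell; an early toy-sized
soma made the band curve so strongly that convex-hull areas overshot the
band area by ~30%, which is a scale artifact, not a property of the
system). The KO-like condition differs from WT-like
by 2–4 gap sectors of 0.5–2 µm depth (60–90° extents, capped by the
recoverability rule) in whole-cell fields and a doubled vesicle density
(20 vs 10 per µm²) in high-mag fields. The magnitudes are package choices
made once to keep the group differences recoverable at desk scale; they are
not claims about the biology. Everything is deterministic in the scene
seed: identical parameters and seed give bit-identical images and truth.

**What the generator does not emulate.** Organelles other than vesicles
(mitochondria, ER), membrane undulations at the nanometre scale,
section-thickness effects, stain variability between blocks, and partial
vesicle profiles from out-of-plane sectioning. Passing tests on synthetic
scenes therefore demonstrate that the measurement and detection machinery
is correct and well-calibrated on fields with these statistics — not that
the trained detector transfers to real micrographs without retraining.

# Morphometry

Measurements follow the manual protocol they automate:

- **Gap profile**: distances from 720 arc-length-uniform points on the
  neuron contour (0.5° steps on a round cell) to the nearest point of the
  SGC inner contour.
- **Three largest gaps**: the three largest local maxima of the circular
  profile separated by at least 20°; the manual protocol takes three
  measurements per neuron at the largest *distinct* gaps, hence the angular
  exclusion. If fewer separated maxima exist the remainder is padded from
  the global order and flagged.
- **Distant-glia flag**: 1 when the largest gap reaches the threshold
  (boundary counts as 1). In manual scoring this is a qualitative
  judgement — glia obviously distant from the neuron or not — with no
  published cutoff; the package's default threshold of 0.25 µm sits an
  order of magnitude above the 30 nm baseline and well below micron-scale
  pathological gaps, and is always reported alongside the output.
- **Diameter**: maximum caliper (Feret) distance over the contour — the
  neuron's largest span in any direction, as a human measures it.
- **Area**: shoelace area of the traced polygon.
- **Circularity**: major/minor axis ratio of the second-moment
  (covariance-equivalent) ellipse of the enclosed region — 1 for a circle,
  >1 elongated. A major-to-minor axis ratio can be defined against several
  ellipse fits (caliper boxes, boundary least squares, area moments); the
  moment ellipse is rotation-stable and exact on polygons, so the package
  uses it, and fixes the convention that values are always ≥ 1 (some
  manual protocols report the reciprocal). Exact polygon moment integrals
  are used, not rasterized approximations.

# The two-stage vesicle detector

**Stage 1 — patch classifier with Grad-CAM.** A small four-conv-block CNN
(8/16/32/32 channels, 3×3 kernels, max-pooling after the first two blocks,
global average pooling, 2-class dense head) classifies 32×32 px patches
(160 nm field at 5 nm/px, about three vesicle diameters) as
vesicle-present vs background. Training: mini-batch 25, at most 500
epochs, augmentation by random resizing up to ±10% and horizontal
reflection, 20% of patches held out for validation. Grad-CAM is computed
at the last convolutional block: channel weights are the spatial mean of
the class-score gradient with respect to the post-ReLU feature maps; the
map is the rectified weighted sum, bilinearly upsampled to patch size and
max-normalised to [0, 1] (an all-zero map is valid when class evidence is
absent). For this GAP-plus-linear head the weights reduce to the dense
weights divided by the map area, which the tests exploit as a closed form.

**Scanning.** The image is tiled with overlapping patches (stride =
patch/2 by default). Tiles whose vesicle probability reaches the
contribution threshold (0.5) add their Grad-CAM maps to a stitched
image-level map (overlaps averaged). Regions of interest are anchored on
the stitched map's local maxima: peaks at or above the ROI threshold,
thinned by non-maximum suppression within 8 px, each spawn a patch-sized
box. Peak-based regions were chosen over connected components because the
peak set only shrinks as the threshold rises — raising the ROI threshold
can never increase the ROI count — whereas a connected region can split
into several. The contribution threshold is deliberately decoupled from
the ROI threshold so the stitched map, and hence the peak hierarchy, is
invariant when the ROI threshold is varied. Tile maps enter the average
weighted by their class probability, and the stitched map is smoothed
(Gaussian, 3 px) before peak extraction; both damp spurious near-threshold
peaks. Two vesicles closer than the suppression radius may share a box;
they are still separated downstream, because counts come from stage-2
instance segmentation, not from ROIs.

Overlap matters: at stride = patch (no overlap) a vesicle at a tile border
is attenuated (zero-padded convolution features weaken Grad-CAM near patch
edges) and a vesicle sharing its only tile with a stronger one is
under-represented (per-patch max normalisation), so non-overlapping scans
undercount. ROI counts are stable (within ~20% per scene) between
overlapped strides such as patch/2 and patch/4; the default is patch/2.

**Stage 2 — per-pixel segmentation.** Within each ROI a second network
(three 3×3 conv layers of 16 channels and a 1×1 classification layer,
full resolution throughout) labels vesicle pixels on 16×16 px tiles
(stride 8, probabilities averaged). Training: mini-batch 100, at most
1,000 epochs, augmentation limited to ±5% resizing plus reflection and
±2 px shift — at the few-pixel scale of a vesicle, stronger augmentation
manufactures artifacts. Connected foreground components of at least 20 px
become instances; the equivalent diameter is `2*sqrt(area/pi)*nm_per_px`;
instances from overlapping ROIs are deduplicated at 5 px centroid distance
(half a nominal vesicle diameter). A second-stage network of this kind
can either label pixels or classify candidate blobs; per-pixel
segmentation is the default here because it also yields the instance
masks and diameters.

**The network engine.** No deep-learning framework is assumed: the layers,
Adam optimiser and backpropagation (verified against numerical gradients to
1e-6 in the tests) are implemented in vectorised R, with convolutions
evaluated as BLAS matrix products over cached im2col index tables. Inputs
are fixed-normalised from [0,1] to [-1,1]. Initialisation is He-scaled;
the optimiser is Adam at learning rate 2e-3 for the default detector.
Early stopping monitors validation accuracy with a 20-epoch plateau
(improvements under 0.2% count as plateau; the best-epoch weights are kept
regardless); the epoch caps above are exactly that — caps. Training is
single-threaded and bit-deterministic in the seed. A GoogLeNet-scale
backbone would add nothing at the 32 px patch size and desk scale this
package targets, so the small CNN is the only backbone.

**Default datasets.** Stage 1 trains on 2,000 patches (half positives
centred on vesicles with ±3 px jitter, half from entirely vesicle-free
windows) drawn from eight high-density (25/µm²) partial-field scenes;
stage 2 on 1,200 16×16 patches with ground-truth masks — in segmentation
the pixels are the effective samples, so fewer patches suffice. The 20%
validation split is a function of the dataset seed alone.

# Density and group statistics

Detected centroids are clustered with DBSCAN (eps 200 nm, minimum 3
points; border points join their nearest core point, a deterministic
variant). The per-cell density divides a vesicle count by a convex-hull
area (µm²) — the smallest convex set containing the vesicles. In the
default `largest_cluster` mode both the numerator and the hull come from
the largest cluster (its count over its occupied area — pairing the total
count with a sub-cluster's hull would overestimate grossly); the
`all_points` mode uses every centroid, and exists because either reading
of "the smallest convex set containing the vesicles" is defensible when
the vesicles are first clustered. With fewer than three
non-collinear points the hull is degenerate and the density is undefined
rather than forced. A cell is "detectable" at ≥3 vesicles — the minimum for a
non-degenerate hull; any such cutoff is a reporting convention and this
one is the least arbitrary available.

Two regimes matter for interpreting hull densities. When the typical
nearest-neighbour spacing (1/√density) approaches the 200 nm clustering
radius, cluster membership is unstable and the largest-cluster estimate
noisy; the group-contrast experiments therefore use the all-points hull,
which at the presets' 10–20 vesicles/µm² separates the 2× conditions with
essentially full power. And for sparse point sets any hull understates the
occupied region (boundary deficit ~ perimeter × spacing), so absolute
density recovery is tested in the dense regime (80–160/µm²) where the
estimator is consistent; cross-condition comparisons remain valid at lower
densities because both groups share the estimator and its bias.

Group comparisons: Pearson chi-square without continuity correction
(df = 1) on the 2×2 detectable-vesicles table (Yates correction available
by flag), the two-sample Kolmogorov–Smirnov test on per-cell densities
(exact enumeration below nx·ny = 10⁴ without ties, asymptotic otherwise —
`stats::ks.test`'s rule, which matches the intended small-sample
behaviour), and Student's t tests for morphometry panels. Summaries are
means ± SEM (SD/√n; a single-value group reports SEM 0 and is flagged). No
multiple-testing correction is applied: each panel carries a single test.

# Problem sizes, runtimes and determinism

The package's default experiment sizes are chosen for a desk-scale,
single-CPU workflow: 20 scenes per condition for morphometry recovery, 20
scenes per density in {1, 3, 5}/µm² for count recovery, 50 replicates of
20 + 20 cells for the KS power experiment, and the training corpus above
(minutes per stage). The full pipeline writes every artifact (scenes,
truth JSON, model bundle JSON, detections JSON, CSV tables) under one
output directory with a manifest of the seed, config digest and file
hashes; re-running with the same configuration and seed reproduces every
CSV/JSON byte-for-byte, which the acceptance suite checks.

# Known limitations

- The detector is trained and validated on the generator's statistics;
  transfer to real micrographs requires retraining on hand-labelled
  patches (the patch-dataset and training interfaces accept any scenes
  with truth in the documented JSON format).
- Nearest-point gap profiles cannot register gaps much deeper than their
  width (see the recoverability rule); such geometries would need a
  normal-ray or medial-axis measure.
- Hull-based density is biased upward for sparse cells (small hulls);
  cross-condition comparisons remain valid because both groups share the
  estimator.
- The per-animal hierarchy of a real study (multiple cells per animal) is
  out of scope; tests are per-cell, as in the panels this mirrors.
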