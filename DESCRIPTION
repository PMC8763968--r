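Package: temquant
Title: Quantification of Neuron-Glia Ultrastructure and Vesicles in TEM Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Synthesizes transmission electron microscopy (TEM)-like scenes of
    sensory neuron somata enveloped by satellite glial cells (SGCs) with full
    ground truth, measures neuron-glia morphometry (membrane gap profiles,
    Feret diameter, area, axis-ratio circularity), detects ~50 nm vesicle
    profiles in the SGC cytoplasm with a two-stage convolutional network
    (patch classifier with Grad-CAM localization followed by a segmentation
    network), converts detections into per-cell vesicle density via
    density-based clustering and convex-hull area, and compares genotype-like
    groups with chi-square, Kolmogorov-Smirnov and t tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    tiff,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
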