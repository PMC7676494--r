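Package: biopsy3d
Title: Label-Free 3D Reconstruction of Cleared Tissue Biopsies from
    Multimodal Transmission Microscopy Z-Stacks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the three-dimensional architecture of optically
    cleared tissue punches from multimodal focal-plane stacks (bright-field,
    dark-field and two epifluorescence channels) without fluorescent staining
    of the tissue itself. Tissue presence is segmented per voxel from the
    local high-spatial-frequency energy of bright-field planes, exploiting
    the physical attenuation of high spatial frequencies with defocus
    distance; internal cavities and tubules are extracted as enclosed
    non-tissue components. Supporting stages cover flat-field calibration,
    drift correction by normalized cross-correlation, Richardson-Lucy
    deconvolution with a bead-derived point-spread function, two-tile
    volumetric stitching via 3D scale-invariant features and robust affine
    estimation, and a transparent ray-casting volume renderer. A synthetic
    phantom generator with ground truth supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    ggplot2,
    rlang,
    stats,
    tiff,
    png,
    yaml,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
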