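Package: vemseg
Title: Unsupervised Instance Segmentation of Cells in Volumetric Electron Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An unsupervised pipeline for instance segmentation of cells in
    serial block-face scanning electron microscopy (SBF-SEM) stacks. The bright
    resin background is segmented per slice (Otsu thresholding over Canny-edge
    super-pixels with morphological cleanup), a Euclidean distance transform
    turns cells into ranked "hills" whose peaks are detected and linked across
    slices into cell tracks, and per-cell regions of interest are cropped. The
    nuclear envelope is segmented by filtered edge detection with bidirectional
    slice propagation, and the plasma membrane by watershed on the distance map
    followed by morphological refinement and protrusion merging. Voxel-wise
    Accuracy and Jaccard metrics evaluate three scenarios (cell excluding
    nucleus, cell including nucleus, nucleus only). A parametric phantom
    generator renders synthetic stacks with voxel-exact ground truth so the
    whole pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    tiff,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
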