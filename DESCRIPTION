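Package: platetalk
Title: Single-Cell Immunofluorescence Quantification and Pathway
    Crosstalk Inference for Multi-Well Plate Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for high-content immunofluorescence
    screens of morphogenic pathway crosstalk (TGF-beta, Wnt, BMP).
    Implements flat-field illumination correction from uniformly
    fluorescent reference wells with detector (dark-frame) subtraction
    and quantile background estimation, automated threshold segmentation
    of nuclei with per-channel intensity features, G1/0 gating by a
    two-component Gaussian mixture fit to total nuclear Hoechst
    intensity followed by median-absolute-deviation quality windows on
    nuclear size and texture, replicate-median response normalization
    anchored to control and canonical-ligand conditions, Welch t-test
    crosstalk calls, and delta-delta-Ct quantification of qPCR
    threshold-cycle tables.  A synthetic plate generator renders
    multi-channel TIFF fields with known ground truth (shading, detector
    offset, nuclear intensities, DNA-content classes, debris) so that
    every stage is validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
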