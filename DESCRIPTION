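Package: biadquant
Title: Quantification of Dual-Color Bimolecular Anchor Detector Microscopy
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Ratiometric quantification of dual-color bimolecular anchor
    detector (BiAD) fluorescence microscopy of single nuclei. Implements the
    two-threshold region-of-interest workflow: maximum-intensity projection of
    multi-channel z-stacks, nucleus and marker-spot segmentation on the locus
    marker channel, per-channel nuclear-background subtraction, the relative
    BiAD signal (background-corrected BiAD spot intensity normalized to the
    corresponding marker spot intensity) with per-cell averaging, allelic
    Xi/Xa classification against an immunostain territory with
    Xa-normalization, control-detector normalization, and group statistics
    (two-tailed unpaired t tests, one-way ANOVA with Tukey post tests,
    boxplot summaries). A synthetic microscopy generator renders nuclei with
    copy-number-scaled marker spots, detector-dependent BiAD amplitudes,
    stain territories, transfection dropout and Poisson plus Gaussian camera
    noise, providing ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tiff,
    EBImage,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: Software, CellBiology, Epigenetics, FeatureExtraction,
    Visualization
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'accessors.R'
    'biadquant-package.R'
    'imaging-io.R'
    'statistics.R'
    'simulate.R'
    'segmentation.R'
    'quantification.R'
    'pipeline.R'
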