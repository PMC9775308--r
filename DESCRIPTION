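Package: skinquant
Title: Volumetric Morphometry of Engineered Skin Equivalents
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantitative 3D image analysis for multi-layer human skin
    equivalent cultures imaged by confocal microscopy. Provides plane-wise
    preprocessing (median filtering, linear intensity rescaling, rolling-ball
    background subtraction), hysteresis segmentation and morphological
    cleanup of anisotropic voxel volumes; epidermal thickness mapping and
    suprabasal marker intensity; lipid (adipose) volume fraction, thickness
    and integrated intensity; vascular network analysis via multiscale
    Hessian vesselness, homotopic 3D skeletonization, Euclidean distance
    transform diameters and a 90%-coverage diffusion length; UVA radiant
    exposure dosimetry and control-normalized group statistics. A seeded
    synthetic phantom generator with exact geometric ground truth supports
    validation of every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
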