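Package: peritoscore
Title: Implantation and Invasion Scoring for Peritoneal Explant Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Quantification of dye-stained cancer cells interacting with
    ex vivo peritoneal explants imaged by two-channel confocal z-stacks
    (red: tracker-stained cells; green: collagen reflectance). Provides a
    synthetic stack generator with planted ground truth, a
    Laplacian-of-Gaussian spot detector for maximum-projection cell
    counting and 3D localization, mesothelial-surface estimation from the
    reflectance channel, the normalized implantation score and the
    deepest-cells invasion score with replicate/observer aggregation and
    group statistics, plus scratch-wound, cell-shape and viability assay
    quantification, orchestrated as a reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
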