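Package: scintihot
Title: Hotspot Detection Pipeline for Whole-Body Bone Scintigraphy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for lesion-level bone-metastasis screening on planar
    whole-body bone scans (Tc-99m MDP scintigraphy). Provides 16-bit scan and
    annotation I/O, a synthetic phantom generator with ground-truth hotspots,
    projection-profile body detection and mean-controlled intensity
    normalization, anterior/posterior view fusion into a three-channel chest
    image, offline intensity-level augmentation, a pluggable hotspot-detector
    backend with a classical CPU reference implementation, an automated
    negative-mining training loop, and lesion- and patient-level
    cross-validated evaluation with shuffle-table aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    jsonlite,
    png,
    tiff,
    tools,
    withr,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
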