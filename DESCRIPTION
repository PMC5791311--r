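Package: migmorph
Title: Automated 3D Microglia Morphometry from Confocal Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Reconstructs and quantifies microglial morphology from
    single-channel confocal Z-stacks. Implements a full analysis chain:
    slice-wise local contrast enhancement, Li minimum-cross-entropy global
    thresholding, morphological mask simplification, Phansalkar local
    thresholding for soma detection, marker-controlled 3D watershed instance
    separation, topology-preserving 3D skeletonization with
    slab/junction/endpoint labelling, conformational Sholl profiles at a
    fixed radial step with per-cell area-under-curve and longest-path
    summaries, rule-based activation and dystrophy classification, and pooled
    nonparametric group comparison (Kruskal-Wallis with Dunn or Holm-Sidak
    post hoc tests). Ships a synthetic phantom generator that rasterizes
    ground-truth branching cells into confocal-like noisy stacks so the whole
    pipeline is testable without microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tiff,
    EBImage,
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
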