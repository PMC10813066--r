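Package: cementmap
Title: Characterization of Hypercementosis from 3D Thickness Maps and Surface Topography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize excessive cementum apposition
    (hypercementosis) on single-rooted human teeth. Computes per-vertex
    cementum thickness maps from paired dentine/cementum surface meshes,
    localizes maxima and minima by root third and side, detects atypical
    apposition shapes (nodes, nodules, overgrowths, ridges, spikes),
    processes confocal-style height maps (non-measured point filling,
    leveling, degree-2 form removal) and scores surface aspect, encodes
    dental visual-scoring systems, classifies teeth into etiological
    groups with a fixed published decision tree, a from-scratch CART
    learner and a from-scratch Factor Analysis of Mixed Data, and ships a
    35-tooth reference dataset together with a synthetic tooth-root and
    height-map generator with analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    rpart
Config/testthat/edition: 3
RoxygenNote: 7.3.3
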