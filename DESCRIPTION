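Package: poreflow
Title: Selectivity-Filter Conformational and Permeation Analysis for K2P Channel Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trajectory analysis for potassium-channel selectivity filters:
    dihedral featurization of the filter (44 backbone and chi1 angles),
    sketch-map nonlinear dimensionality reduction with landmark selection and
    out-of-sample projection, DBSCAN clustering of the low-dimensional map,
    carbonyl-flip state classification and population tables, K+ permeation
    event detection with single-channel conductance estimation, TM2-TM4
    up/down gating classification, and lipid cavity-penetration analysis.
    Includes synthetic-trajectory generators with known ground truth (Markov
    switching dihedral dynamics, planted permeation events, telegraph gating,
    lipid excursions) for end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
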