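Package: glyccs
Title: Gas-Phase Structure Assignment for Glycan Ions from Ion-Mobility
    Collision Cross Sections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An in-silico workflow for assigning gas-phase structures and
    nitrogen collision cross sections (CCS) to singly charged glycan ions
    observed in drift-tube ion-mobility mass spectrometry. The pipeline
    enumerates titratable sites to build [M+H]+ and [M-H]- charge models,
    ranks them with a classical surrogate energy backend and retains
    candidates inside a relative-energy window, generates and clusters
    torsion-sampled conformer ensembles, computes CCS by the projection
    approximation and the trajectory method in nitrogen buffer gas, and
    scores Boltzmann-weighted CCS values against bundled experimental
    drift-tube reference tables with percent-error and success-rate
    statistics for isomer discrimination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    igraph,
    yaml,
    pracma,
    ChemmineR,
    bio3d,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
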