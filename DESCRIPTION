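Package: bcellfate
Title: Discrete and Continuous Dynamics of the B-Cell Terminal
    Differentiation Regulatory Network
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Qualitative dynamical modelling of the gene regulatory network
    controlling terminal differentiation of B lymphocytes into germinal
    center, memory and plasma cells.  Ships a curated 22-node logical model
    of the Naive/GC/Mem/PC decision as a packaged network, and provides two
    dynamical engines over arbitrary logical networks: a synchronous Boolean
    engine with exhaustive bit-parallel attractor enumeration and exact
    basin-of-attraction measurement, and a fuzzy-logic continuous engine in
    which each rule is converted to a min/max/(1-x) expression driving a
    normalised sigmoid ordinary differential equation.  Supports permanent
    clamping for loss- and gain-of-function mutant screens, transient pulses
    of extracellular signals for differentiation protocols, perturbation-based
    discovery of intermediate attractors, cell-fate map construction, random
    Boolean network generation for property testing, and import/export of
    BoolNet-style rule files, an SBML-qual subset, SIF and GraphML.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    compiler,
    deSolve,
    igraph,
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
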