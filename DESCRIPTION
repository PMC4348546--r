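Package: fluxcanal
Title: Flux-Based Auxin Transport and Canalization on Cell Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and steady-state analysis of flux-based auxin
    transport models of plant vascular self-organization. Cells are nodes of
    a tissue graph; PIN efflux carriers on each membrane respond to the net
    auxin flux through it, creating the positive feedback that canalizes
    flow into discrete veins. The package integrates the full, extended
    (cytosolic PIN cycling) and simplified slow-PIN model variants with
    detection of convergence, sustained oscillation and finite-time
    blow-up of membrane PIN; extracts the steady-state orientation graph
    and classifies its topology (sink-rooted forests, cycles, necessary
    stability conditions); performs numerical linear stability analysis;
    and computes exact sink-driven tree solutions and source-driven vein
    solutions with classification of the with-gradient and
    against-gradient regimes. Includes programmatic generators for grid,
    line and random-tree tissues and for the standard study scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
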