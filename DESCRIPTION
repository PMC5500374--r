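Package: snaresat
Title: SNARE-Regulated Vesicle Traffic Networks via Boolean Satisfiability
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Executable semantics of the Rothman-Schekman-Sudhof (RSS)
    abstraction of eukaryotic vesicle traffic: compartments and vesicles
    as a labeled directed multigraph, SNARE-pairing fusion rules under a
    hierarchy of regulation regimes, steady-state flux cycles, and
    k-edge-connectivity analysis. A conflict-driven clause-learning SAT
    solver (bundled, in C++) decides feasibility of traffic networks
    within finite bounds, supporting necessity and sufficiency workflows
    for graph-connectivity conjectures, exact isomorphism-free
    enumeration of simple and multigraph topologies, a brute-force
    oracle for cross-validation, and JSON/DOT/GraphML input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
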