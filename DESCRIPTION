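Package: swarmrefine
Title: Decomposition-Based Multi-Objective Particle Swarm Refinement of
    Protein Backbone Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Refines protein backbone models by multi-objective particle
    swarm optimization over backbone torsion angles. The multi-objective
    energy landscape is decomposed into scalar subproblems via
    simplex-lattice weight vectors and penalty-based boundary intersection
    (PBI) aggregation with an adaptive penalty schedule; a Pareto archive
    collects non-dominated conformations and refined models are selected by
    knee-oriented expected-utility ranking under random weight sampling.
    Includes an internal-to-Cartesian coordinate engine for backbone
    geometry, pluggable surrogate energy functions, benchmark objective
    landscapes with known Pareto fronts, CA-based RMSD and approximate
    GDT-TS model-quality metrics, and synthetic refinement fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
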