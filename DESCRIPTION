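Package: conndyn
Title: Whole-Brain Neural Mass Dynamics and Dynamic Range on Weighted Connectomes
Version: 0.2.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of large-scale brain dynamics on weighted
    structural connectomes. Implements the reduced Wong-Wang dynamic mean-field
    model and the Wilson-Cowan model with Euler-Maruyama integration (optional
    conduction delays and heterogeneous excitatory inputs), excitability
    response functions and their neural dynamic range, Balloon-Windkessel
    haemodynamics with simulated functional connectivity, intrinsic-timescale
    estimation by exponential autocorrelation fitting, a networked
    drift-diffusion decision model driven by the connectome Laplacian, and
    weighted graph metrics (Onnela clustering, regional path length,
    small-world propensity, Louvain modularity). Includes a synthetic
    connectome and cohort generator with modular, hemispheric and
    anterior-posterior gradient structure, plus connectome I/O, group
    averaging with consistency thresholding, density matching and
    cross-species edge classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    minpack.lm,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'connectome-io.R'
    'decision-model.R'
    'dynamic-range.R'
    'graph-metrics.R'
    'neural-sim.R'
    'hemodynamics.R'
    'timescale.R'
    'synthetic.R'
    'pipeline.R'
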