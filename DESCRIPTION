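Package: SynGold
Title: Spatial Statistics of Immunogold-Labeled Synaptic Receptors and
    Desk-Scale Receptor Activation Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing point annotations of gold-labeled
    glutamate receptors, docked vesicles and exocytic pits within
    synaptic active zones and postsynaptic densities from electron
    micrographs. Implements normalized lateral distances in single 2D
    profiles, serial-section 3D distances with fractional-area
    correction, per-synapse K-means cluster analysis with knee-point
    selection and randomization null models, the nonparametric test
    battery used for such data, a synthetic-data generator with a
    random-sectioning forward model for validation against known ground
    truth, and a mean-field/stochastic simulator of AMPA and NMDA
    receptor activation by spatiotemporally patterned glutamate release
    with voltage-dependent magnesium block.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'SynGold-package.R'
    'annotations-io.R'
    'clustering.R'
    'inferential-stats.R'
    'pipeline.R'
    'receptor-sim.R'
    'spatial-metrics.R'
    'synthetic-data.R'
    'utils.R'
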