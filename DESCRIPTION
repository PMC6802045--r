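Package: tigerscape
Title: Spatially Explicit Simulation of Tiger Territories Under Prey Depletion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An agent-based model of territorial tiger population dynamics on
    raster landscapes of prey biomass production, together with an experiment
    engine that depletes prey along spatial gradients from the protected-area
    border. Provides the stylized circular landscape, synthetic heterogeneous
    landscape generation, six distance-based depletion probability functions
    with a multi-pass stochastic depletion algorithm, a global Moran's I
    heterogeneity metric, a monthly scheduler for female territory formation
    and male mate acquisition, a factorial experiment runner, and gamma and
    negative binomial GLM analysis of simulation outcomes.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    MASS,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
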