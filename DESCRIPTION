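Package: safsim
Title: Stochastic Simulation of Recurrent Genomic Selection in Safflower
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a recurrent genomic-selection breeding program for two
    correlated traits (grain yield and seed oil content) in safflower, from a
    diverse founder panel through biparental crossing, single-seed descent and
    genomic prediction. Marker effects are estimated with a BayesR
    four-component mixture Gibbs sampler; candidates are selected by
    single-trait truncation, an equal-weight standardized index, or an index
    combined with genetic-algorithm mate allocation that penalizes genomic
    co-ancestry. Tracks genetic gain per cycle in genetic standard-deviation
    units and inbreeding from the VanRaden genomic relationship matrix, and
    reproduces gain tables and inbreeding trajectories for strategy
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    ggplot2,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
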