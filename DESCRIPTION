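Package: micronet
Title: Network-Based Characterization of Microbial Communities from
    Compositional Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds and compares genus-level microbial co-occurrence
    networks from 16S rRNA count tables. Implements compositional
    preprocessing (taxon/sample filtering, Bayesian-multiplicative zero
    replacement, centered log-ratio transformation, alpha diversity),
    SparCC correlation inference with significance-based edge
    sparsification under local false discovery rate control, global and
    local network properties, centrality-based hub detection, two core
    microbiota definitions (prevalence/abundance and hub-quantile based),
    graphlet orbit counting up to four nodes with graphlet correlation
    matrices and between-group Fisher z comparison, and permutation tests
    for network property differences between sample groups. A synthetic
    data generator with planted correlation structure supports end-to-end
    validation and parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    vegan,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
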