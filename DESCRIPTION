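Package: cecaphylo
Title: Phylogenetic Comparative Analysis of Avian Cecal Allometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for testing phylogenetic signal and fitting phylogenetic
    generalized least squares (PGLS) regressions of avian cecal length on
    body mass with dietary, clade, and flight-ability cofactors. Implements
    maximum-likelihood estimation of Pagel's lambda for continuous
    characters, permutation tail probability (PTP) tests based on Fitch
    parsimony length for categorical characters, GLS under independent,
    Brownian-motion, and Ornstein-Uhlenbeck residual covariance with AIC
    model selection, branch-length assignment schemes for composite
    phylogenies, and a synthetic-data generator that reproduces the
    statistical structure of the study design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools,
    nlme,
    phangorn,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
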