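Package: shannonpop
Title: Bias-Aware Shannon Diversity Estimation for Population Genetics
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation of the Shannon diversity index on multiallelic
    genetic markers with four estimators: the maximum-likelihood plug-in,
    the Zahl (1977) jackknife, the Chao-Shen (2003) coverage-adjusted
    Horvitz-Thompson estimator and the Chao et al. (2013) estimator, plus
    Nei's gene diversity. Includes GENEPOP input, a coalescent simulator
    for unlinked microsatellite loci under a bounded stepwise mutation
    model with piecewise-constant demography (bottleneck scenarios), and a
    resampling framework that quantifies the sample-size bias (rB) and
    mean relative squared error (MRSE) of each estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
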