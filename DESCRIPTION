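Package: sphmm
Title: Semi-Parametric Hierarchical Mixture Modelling of GWAS Summary
    Statistics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the proportion of disease-associated SNPs and their
    effect-size distribution from genome-wide association study (GWAS)
    summary statistics, using an empirical-Bayes two-group mixture model
    in which the non-null effect sizes follow a non-parametric discrete
    prior on a fixed grid of log odds ratios, fitted by
    expectation-maximization.  From the fitted model the package predicts
    the number of genome-wide-significant SNPs in a future case/control
    study of any size, inverts the discovery curve to obtain the sample
    size required for a target number of discoveries, and quantifies
    uncertainty by parametric bootstrap.  Utilities cover reading and
    harmonizing summary-statistic files, random LD pruning to a nearly
    independent SNP set, and a synthetic-data generator that reproduces
    the model's sampling assumptions for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
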