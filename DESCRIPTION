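Package: cytotaxa
Title: Cytokine-Microbiota Association by Dirichlet-Multinomial Regression
    with Bayesian Variable Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-step association analysis between tissue cytokine panels and
    mucosal microbiota compositions. Step one ranks cytokines by marginal
    evidence from single-covariate Dirichlet regressions with likelihood-ratio
    tests (sure independence screening); step two fits a Dirichlet-multinomial
    regression with Bayesian variable selection via a hard-thresholding prior
    and a Metropolis-within-Gibbs sampler, reporting posterior probabilities
    of inclusion and conditional posterior means. Also provides the
    formula-level microbiome preprocessing the analysis relies on (taxonomic
    aggregation, top-k composition response, limit-of-quantification
    censoring), per-sample alpha-diversity and coverage statistics, exact
    rarefaction expectations, a dendrogram-based paired-sample check, and a
    synthetic paired tumor/healthy study generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
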