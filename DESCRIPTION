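Package: climexpr
Title: Modeling Climate-Driven Gene Expression Dynamics in Field Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to explain field gene-expression dynamics by linear
    combinations of engineered environmental and developmental (ED)
    parameters. Implements co-expression clustering with partitioning around
    medoids under correlation distance, engineering of windowed weather
    statistics (averages, non-linear solar transforms, recent-change deltas,
    fluctuation residuals from seasonal decomposition, soil moisture and
    developmental stage), lasso stability selection of candidate parameters,
    exhaustive piecewise linear model selection across field and season
    contexts compared by BIC on cross-validated residuals, field-response
    classification of clusters, and sign-constrained transfer of models to
    independent datasets. Ships a synthetic-data generator with known
    ground-truth equations so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    cluster,
    DESeq2,
    glmnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
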