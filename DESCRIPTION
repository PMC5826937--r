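Package: plasmastab
Title: Time-Series Stability Analysis of the Plasma Metabolome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis of plasma metabolome stability under sub-optimal
    freezing from deconvolved LC-MS feature tables. Implements QC-based
    feature filtering (dilution-series response, QC replicate coefficient
    of variation, missingness), preprocessing (K-nearest-neighbour
    imputation, constant-sum normalisation, generalised log transform,
    autoscaling), univariate time-series screening (one-way
    repeated-measures ANOVA, paired t-tests versus baseline with
    Benjamini-Hochberg correction), feature ranking by a moderated
    one-sample Hotelling T-squared statistic, and an elastic-net-penalised
    Poisson regression - fitted from scratch by iteratively reweighted
    least squares with cyclic coordinate descent - that predicts storage
    time from the metabolite profile and ranks the features driving the
    prediction. A synthetic-data generator emulates the pooled-plasma
    storage design (11 time points, replicate aliquots, QC injections and
    a QC dilution series) with per-feature ground truth so that every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
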