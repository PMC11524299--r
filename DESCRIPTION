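Package: fungraph
Title: Functional Mapping and Genetic Interaction Networks for Growth Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps quantitative trait loci (QTLs) for longitudinal growth traits by
    genotype-grouped maximum likelihood under a logistic growth mean and a
    first-order structured antedependence (SAD(1)) residual covariance, with
    likelihood-ratio scans and permutation-based genome-wide thresholds.
    Converts per-marker fits into age-varying genetic effect curves, clusters
    the curves into a module hierarchy by an EM mixture with BIC model
    selection, and reconstructs a multilayer, bidirectional, signed and
    weighted genetic interaction network by decomposing each marker's effect
    dynamics into an independent Lotka-Volterra component and sparse dependent
    components selected by LASSO and fitted by fourth-order Runge-Kutta
    nonlinear least squares. Includes a synthetic-data generator with planted
    QTLs and planted interaction networks for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pracma,
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
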