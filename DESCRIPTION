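Package: ngvs
Title: Network-Based Group Variable Selection for eQTL Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Penalized multi-trait regression for expression quantitative
    trait locus (eQTL) detection. Marker sets formed from linkage
    disequilibrium structure are selected jointly across a gene
    co-expression network by combining a group-lasso penalty over marker
    sets with a graph-Laplacian smoothness penalty over traits. Includes a
    block co-ordinate gradient descent group-lasso solver, the
    network-augmentation reformulation of the penalized criterion, SNP-set
    kernels (linear, polynomial, Gaussian, IBS, weighted IBS),
    adjacent-interaction and covariate model builders, a three-stage QTL
    selection-order procedure, F2-cross simulation generators with
    signal-to-noise control, and benchmarking utilities
    (sensitivity/specificity, ROC, true/false positive counts).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    Matrix,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
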