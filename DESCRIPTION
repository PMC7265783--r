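Package: PanPathNet
Title: Bayesian Pathway Network Inference, Sample-Specific Pathway
    Scoring and Drug-Response Prediction for Pan-Cancer Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers cancer-lineage-specific protein-protein pathway
    networks from reverse-phase protein array (RPPA) style expression
    matrices by Bayesian graphical regression with spike-and-slab edge
    selection, deconvolves the fitted networks into per-sample pathway
    activation/neutral/suppression scores, compares network circuitry
    between patient tumors and cell-line model systems (edge
    consistency, connectivity scores with a permutation null, lineage
    linking), matches patient cancer types to avatar cell-line lineages
    by correlation of network aberration scores, clusters samples with
    a gap-statistic-selected complete-linkage solution, and trains
    Bayesian additive regression tree classifiers of binary drug
    sensitivity on the pathway aberration scores.  A synthetic-data
    generator with known ground-truth networks, sample statuses and
    drug-response drivers makes every stage testable without external
    cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    ape,
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    pROC,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
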