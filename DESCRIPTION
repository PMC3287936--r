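Package: rarepath
Title: Rare-Variant Collapsing, Pathway Enrichment and Boosted SNP Screening for Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Case-control analysis of rare and common genetic variants:
    Hardy-Weinberg quality control in controls and population stratification
    by identity-by-state multidimensional scaling; rare-variant collapsing
    (burden) association over genes and overlapping sliding windows with
    Pearson chi-square or Fisher exact tests; mapping of unit-level p-values
    to per-gene scores by five statistics; gene-set (pathway) analysis with
    the mean log p-value statistic and a gene-resampling permutation null;
    and stochastic gradient boosting of affection status on SNP dosages and
    covariates with split-gain variable importance. Includes a seeded
    generator for a mini-exome-like synthetic cohort (three-population
    Balding-Nichols structure, rare-skewed allele-frequency spectrum,
    pathway-concentrated causal genes) so the whole pipeline is testable
    without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr,
    xgboost
Config/testthat/edition: 3
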