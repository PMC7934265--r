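Package: episcore
Title: Genome-Wide Epistasis Screening and Epistasis Risk Scores for
    Case-Control Phenotypes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide SNP-SNP interaction analysis of binary
    disease phenotypes: genotype and sample quality control (missingness,
    minor-allele frequency, Hardy-Weinberg exact test, heterozygosity,
    annotation-based SNP selection), exhaustive pairwise interaction
    screening with three contingency-table tests (additive logistic
    regression interaction, BOOST log-linear likelihood ratio, and a
    joint-effects odds-ratio comparison) under a 3x3x2 cell-count filter
    with pooled false-discovery-rate control and linkage-disequilibrium
    pruning, multifactor-dimensionality-reduction effect tables, epistasis
    risk scores (ERS), polygenic risk scores (PRS) and their weighted
    combination (CRS), permutation-based selection of predictive
    interactions, and survival / ROC evaluation of risk strata. Includes a
    synthetic genotype-phenotype simulator with planted penetrance-table
    epistasis so the full pipeline is testable without restricted cohort
    data, and PLINK1 binary input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    survival,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
biocViews: GenomeWideAssociation, SNP, GeneticVariability, Epistasis,
    Software, StatisticalMethod
RoxygenNote: 7.3.3
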