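Package: stepreins
Title: Single-Step Genomic Evaluation of Equine Stature
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-step genomic evaluation (ssGBLUP) for withers height in
    multi-breed horse populations. Builds pedigree (A), genomic (G) and
    combined (H) relationship matrices, fits the single-step animal model in
    its Cholesky-transformed equivalent form by Gibbs sampling to obtain
    genomic breeding values, prediction error variances and reliabilities,
    and performs leave-one-chromosome-out and conditional mixed-linear-model
    association scans with per-component variance partitioning. Includes
    SNP quality control with seeded allele-frequency imputation, PLINK
    ped/map and bed/bim/fam input/output, population-structure diagnostics
    (GRM principal components, linkage disequilibrium), and a multi-breed
    pedigree/genotype/phenotype simulator so the whole pipeline can be
    exercised end to end without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
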