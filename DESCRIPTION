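Package: mitocohort
Title: Mitochondrial Genome Cohort Characterization and Median-Regression
    Association Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cohort-scale analysis of human mitochondrial DNA
    (mtDNA). Calls nucleotide variants by global pairwise alignment of whole
    mitochondrial genomes against the revised Cambridge Reference Sequence
    coordinate system, annotates substitutions with gene, synonymy,
    transition/transversion and ambiguity status under the vertebrate
    mitochondrial genetic code, enumerates the complete space of possible
    synonymous and nonsynonymous substitutions, and computes mutational
    diversity, volume, density, relative diversity, momentum, amino-acid
    change bias and physicochemical-change metrics over gender-, age- and
    immune-stratified subpopulations. Includes a genome-wide association
    scan of substitutions against CD4+ T-cell outcomes based on least
    absolute deviation (median) regression with case-resampling bootstrap
    inference and Bonferroni correction, plus a fully synthetic cohort
    generator (sequences, metadata and outcomes) for testing and
    calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
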