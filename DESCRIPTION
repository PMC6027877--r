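Package: hsratmap
Title: Sex-Specific Genetic Map Construction and QTL Reanalysis for
    Heterogeneous Stock Rats
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for building and refining sex-specific genetic linkage
    maps from dense pedigree genotypes in heterogeneous stock (HS) rat
    cohorts. Includes a cohort simulator with fully known crossover ground
    truth, genotype quality control (monomorphic removal, Mendelian-error
    and segregation-distortion filtering, windowed marker thinning),
    per-interval recombination-fraction estimation with Haldane or Kosambi
    mapping functions, two-stage map cleaning (local-regression residual
    filtering of errant markers followed by monotone cubic-spline
    modelling of centimorgan versus physical position), per-kilobase
    recombination-rate resources and chromosome summaries, and F2
    interval-mapping QTL scans by multiple imputation with permutation
    thresholds and Bayes credible intervals for comparing maps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
LinkingTo: Rcpp
biocViews: Genetics, SNP, LinkageDisequilibrium, QualityControl, Software
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
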