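Package: tetragp
Title: Genomic Prediction and Association Mapping for Autotetraploid Crops
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for genomic prediction and genome-wide association in
    autotetraploid species genotyped by sequencing. Converts per-marker
    reference/alternative read counts into allele-dosage calls through a
    binomial posterior that accounts for sequencing error, builds
    autotetraploid relationship matrices (additive, digenic dominance,
    additive-by-additive epistatic, full tetraploid) and Gaussian kernels,
    fits kernel mixed models and Bayesian whole-genome regressions (BayesA,
    BayesC-pi, Bayesian LASSO) by Gibbs sampling, selects training sets by
    the CDmean criterion, and scans markers under additive, simplex- and
    duplex-dominance gene-action codings with a Li-Ji multiple-testing
    threshold. A synthetic tetraploid population generator (population
    structure, GBS-like read counts, multi-environment field trials)
    supports simulation studies and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    graphics,
    lme4,
    vcfR,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
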