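Package: bayesgc
Title: Genomic Prediction with GBLUP, BayesC and BayesGC
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Genomic prediction of breeding values for traits with repeated
    records, comparing GBLUP, BayesC and BayesGC (a polygenic term plus
    Bayesian variable selection fitted jointly). Provides VanRaden
    method-1 genomic relationship matrices, collapsing of per-parity yield
    deviations into weighted single records via the effective number of
    records, a prior-partitioning calculus that maps the fraction of
    genetic variance per fitted SNP (Fr) and the marker/polygenic split
    (q) into inclusion probabilities and effect variances, single-site
    Gibbs samplers with indicator variables, youngest-animal validation
    splits, and accuracy/dispersion-bias statistics. A synthetic-data
    generator emulates the sow maternal-trait study design so the whole
    pipeline is testable without proprietary data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
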