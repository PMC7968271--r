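Package: spectrakin
Title: Multi-Source Prediction of Milk Protein Traits from Infrared
    Spectra, Genotypes and Pedigree
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting milk protein composition by integrating
    milk Fourier-transform infrared (FTIR) spectra, SNP genotypes, pedigree
    and on-farm covariates. Implements spectral, genomic (VanRaden method 1)
    and pedigree (numerator) relationship matrices, Bayesian multiple kernel
    learning via Gibbs sampling, multilayer BayesB with separate mixture
    priors on the wavenumber and SNP layers, a partial least squares
    baseline, a seven-model covariate catalogue, repeated random
    sub-sampling and herd-blocked cross-validation, and a calibrated
    synthetic cow-cohort generator for testing every component without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
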