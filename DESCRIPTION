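Package: t2relax
Title: Multi-Compartment Transverse Relaxation (T2) Analysis of Tumour Specimens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative transverse-relaxation (T2) analysis of
    multi-echo magnitude MRI of tumour specimens. Simulates multi-echo decay
    images with known intra-/extra-cellular compartment structure and Rician
    noise; fits single-compartment (mono-exponential) T2 maps by voxel-wise
    non-linear least squares; fits two-compartment (bi-exponential) models
    either voxel-independently or with a Bayesian algorithm that couples
    neighbouring voxels through a Gaussian Markov random field prior;
    summarizes whole-tumour region-of-interest relaxometry with necrotic-core
    exclusion; and runs normality-gated group comparisons and correlations
    against clinical covariates such as the Ki-67 proliferation index.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
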