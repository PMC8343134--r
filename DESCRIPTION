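Package: envgblup
Title: Multi-Environment Genomic Prediction with Environmental Covariate Kernels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Kernel-based genomic prediction for multi-environment plant
    breeding trials. Builds genomic (G = XX'/p) and environmental
    (Omega = WW'/q) relationship matrices from marker dosages and daily
    weather covariates, fits Bayesian multi-kernel mixed models with main
    genomic effects, naive genotype-by-environment interactions, and
    covariate-informed reaction-norm interactions via an eigenbasis Gibbs
    sampler (with a deterministic fixed-variance BLUP mode), and evaluates
    prediction of untested genotypes in untested environments (CV00) over
    all training-environment subsets. Ships a nested-association-mapping
    style trial simulator so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
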