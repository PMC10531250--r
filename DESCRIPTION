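Package: hybridgp
Title: Multi-Trait Bayesian Kernel Genomic Prediction for Hybrid Breeding
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multi-trait genomic prediction of hybrid performance from
    parental marker data, built around a Gibbs sampler for a matrix-variate
    mixed model with general combining ability (GCA), specific combining
    ability (SCA) and kernel-by-year interaction terms. Supports linear
    (GBLUP), Gaussian and arc-cosine (deep) kernels, three ways of
    incorporating parental phenotypic information (none, parental means, or
    estimated breeding values as covariates), marker quality control,
    untested-hybrids-in-tested-years cross-validation with NRMSE and
    relative-efficiency reporting, and a synthetic hybrid-trial generator
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
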