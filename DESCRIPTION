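Package: charrdiv
Title: Multivariate Divergence Analysis of Arctic Charr Morphs and Their Hybrids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying multivariate phenotypic divergence between two
    sympatric Arctic charr (Salvelinus alpinus) morphs and their first-generation
    hybrids in a common-garden design. Provides a synthetic-data generator with
    known ground truth (cross types, full-sib families, developmental stages,
    seven focal traits, repeated behavioural trials, 20-landmark head
    configurations with a shared allometric axis), geometric-morphometric
    preprocessing (curve resampling, polygon areas, generalized Procrustes
    analysis, morphological disparity, randomized-residual permutation
    regression, phenotypic trajectory analysis), a Gibbs-sampler engine for
    Bayesian multi-response linear mixed models with Gaussian and latent-probit
    binary responses, repeatability on the latent and data scales, phenotypic
    variance-covariance (P) matrix comparison (total variance, eccentricity,
    eigenvector angles, Krzanowski common subspaces with resampling nulls), and
    two-block partial least squares between head shape and univariate traits
    with permutation effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    pracma,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    lme4
Config/testthat/edition: 3
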