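Package: lgctraj
Title: Latent Growth Curve Trajectories of Regional Brain Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Longitudinal growth-curve analysis of regional brain-volume
    decline in aging cohorts. Provides a synthetic-cohort generator with
    missing-at-random dropout, intercept-based percent scaling, optimal
    one-dimensional k-median time binning, maximum-likelihood linear
    random-intercept/random-slope models with likelihood-ratio tests,
    subject-level influence diagnostics (Cook's distance and log-likelihood
    contributions) with an exclusion rule, 20-year decline extrapolation
    with subject-resampling bootstrap and pairwise faster-decline masses,
    a Bayesian bivariate growth model (Gibbs sampler with inverse-Wishart
    priors) yielding slope-slope correlations and plausible values, and
    principal component analysis of person-specific slope estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lme4,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
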