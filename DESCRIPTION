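Package: blmmcor
Title: Correlation Between Two Longitudinal Outcomes via Bivariate Linear
    Mixed Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits the bivariate linear mixed model (BLMM) that links two
    longitudinal outcomes through a joint normal distribution of their
    random intercepts and slopes, by profiled maximum likelihood with a
    log-Cholesky covariance parameterization and either independent or
    correlated residuals.  Provides the three correlation summaries used
    to describe joint evolution of the outcomes: the correlation between
    random effects ("association of evolution"), the marginal correlation
    as a function of time ("evolution of association"), and the
    conditional marginal correlation within the subpopulation whose
    first-outcome intercept and slope exceed clinical thresholds,
    estimated by parametric bootstrap from the fitted joint distribution.
    Includes a naive pointwise Pearson estimator, clustered empirical
    bootstrap confidence intervals, and a two-class mixture simulator for
    quantifying how latent population heterogeneity distorts each
    correlation summary.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    optparse
Suggests:
    nlme,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
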