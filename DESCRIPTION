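Package: zicmpreg
Title: Two-Level Zero-Inflated Count Regression with Conway-Maxwell-Poisson Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood estimation of two-level (cluster random
    intercept) count regression models for survey data with many zeros and
    overdispersion: Poisson, negative binomial, Conway-Maxwell-Poisson, and
    their zero-inflated mixtures, with city-level random intercepts in both
    the zero and the count part. Provides a numerically robust
    Conway-Maxwell-Poisson distribution (log-space truncated series
    normalizer, pmf, moments, sampling), adaptive Gauss-Hermite quadrature
    for the marginal likelihood, Wald standard errors, goodness-of-fit
    indices (log-likelihood, deviance, AIC, BIC, MSE), odds-ratio and
    rate-ratio effect tables, descriptive city and group summaries, and a
    synthetic generator emulating the cluster structure and covariate
    marginals of the Khuzestan Daily Smoking Consumption Survey.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    glmmTMB,
    knitr
Config/testthat/edition: 3
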