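Package: ssindbayes
Title: Bayesian Variance-Component Prior Comparison for Partially Nested Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte-Carlo machinery for studying Bayesian estimation of treatment
    and nesting effects in small-sample partially nested (SSIND) designs, where
    treatment-arm subjects are clustered but control-arm subjects are mutually
    independent. Provides a seeded generator for partially nested two-arm data,
    a Metropolis-within-Gibbs sampler for the heteroscedastic multilevel model
    under matched gamma or uniform priors on the variance components, the four
    standard evaluation indices (convergence rate, credible-interval coverage,
    bias, RMSE), and an experiment runner that sweeps a condition grid and emits
    grand, marginal and prior-recommendation summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
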