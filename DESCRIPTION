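Package: erpdcm
Title: Bayesian Inversion of a Neural Mass Model of Event-Related Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Dynamic causal modelling of event-related potentials with a
    three-population neural mass model. Provides the nine-state delay-approximated
    ODE forward model with Euler integration and forward-sensitivity gradients,
    a seeded synthetic-observation generator, Gamma priors with a Gaussian
    likelihood, gradient-based posterior inference (No-U-Turn sampling,
    automatic-differentiation variational inference with mean-field and
    full-rank Gaussian guides, and the Laplace approximation), convergence
    diagnostics (rank-normalized split R-hat, bulk and tail effective sample
    size, posterior z-scores), model comparison (AIC, BIC, WAIC, Pareto-smoothed
    importance-sampling leave-one-out cross-validation, variational free energy),
    predictive stacking of chains, and orchestration of the associated
    simulation experiments.
License: MIT
Encoding: UTF-8
Imports: Rcpp, stats, utils, graphics, grDevices, jsonlite, yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
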