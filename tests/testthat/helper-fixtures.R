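# Shared fixtures, built lazily and cached across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

study_observation <- function() {
  fixture("obs", function() generate_observation(seed = 1))
}

study_model <- function() {
  fixture("model", function() erp_model(study_observation()))
}

# Small but converged NUTS fit reused by diagnostics / methods tests.
small_nuts_fit <- function() {
  fixture("small_nuts", function()
    run_nuts(study_model(),
             sampler_config(n_chains = 2, n_warmup = 100, n_samples = 100,
                            init_strategy = "prior_tails", seed = 42)))
}

# Hand-built erp_samples object from an explicit chains x iters x params array.
samples_from_array <- function(arr, pointwise = NULL, method = "manual") {
  if (is.null(pointwise))
    pointwise <- array(0, c(dim(arr)[1], dim(arr)[2], 1))
  erpdcm:::new_erp_samples(arr, pointwise, list(), method)
}

# Conjugate normal-normal toy: prior theta ~ N(mu0, tau0^2), y_i ~ N(theta,
# sigma^2). Closed-form posterior and evidence used as oracles.
conjugate_toy <- function(y, mu0 = 0, tau0 = 1, sigma = 1) {
  n <- length(y)
  prec <- 1 / tau0^2 + n / sigma^2
  post_var <- 1 / prec
  post_mean <- post_var * (mu0 / tau0^2 + sum(y) / sigma^2)
  # log marginal likelihood of the linear-Gaussian model
  log_evidence <- sum(dnorm(y, 0, 1, log = TRUE)) # placeholder, overwritten below
  # y ~ N(mu0 * 1, sigma^2 I + tau0^2 J): evaluate exactly
  Sig <- diag(sigma^2, n) + tau0^2
  log_evidence <- -0.5 * (n * log(2 * pi) +
                          determinant(Sig, logarithm = TRUE)$modulus +
                          t(y - mu0) %*% solve(Sig, y - mu0))
  lp_fun <- function(z) {
    th <- z[1]
    list(value = dnorm(th, mu0, tau0, log = TRUE) +
           sum(dnorm(y, th, sigma, log = TRUE)),
         grad = -(th - mu0) / tau0^2 + sum(y - th) / sigma^2)
  }
  list(post_mean = post_mean, post_sd = sqrt(post_var),
       log_evidence = as.numeric(log_evidence), lp_fun = lp_fun,
       y = y, sigma = sigma, mu0 = mu0, tau0 = tau0)
}

flat_draws_test <- function(s) erpdcm:::flat_draws(s)

flat_pointwise_test <- function(s) erpdcm:::flat_pointwise(s)
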