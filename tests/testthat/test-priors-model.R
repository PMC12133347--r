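# Gamma priors, tail sampling, the Bayesian model, transforms and gradients.

test_that("default prior set matches the documented shape/scale table", {
  pr <- erp_priors()
  expect_identical(pr$parameter,
                   c("g1", "g2", "g3", "g4", "delta", "tau_e", "tau_i",
                     "h_e", "h_i", "u"))
  expect_equal(pr$shape[pr$parameter == "g1"], 18.16)
  expect_equal(pr$scale[pr$parameter == "g1"], 0.03)
  expect_equal(pr$shape[pr$parameter == "h_i"], 20.44)
  expect_equal(pr$scale[pr$parameter == "h_i"], 0.96)
  mu <- prior_mean(pr)
  expect_true(all(is.finite(mu)) && all(mu > 0))
  # prior means sit at the magnitude of the generative values
  expect_true(all(abs(log(mu / nmm_params())) < log(2.5)))
})

test_that("log prior is the sum of marginal Gamma terms and respects support", {
  pr <- erp_priors()
  th <- nmm_params()
  by_hand <- sum(dgamma(as.numeric(th), shape = pr$shape, scale = pr$scale,
                        log = TRUE))
  expect_equal(log_prior(th, pr), by_hand, tolerance = 1e-12)
  bad <- as.numeric(th); bad[3] <- -0.1
  expect_identical(log_prior(bad, pr), -Inf)
  # reduced-mask entries contribute nothing
  th0 <- as.numeric(th); th0[1] <- 0
  expect_equal(log_prior(th0, pr, reduced = "g1"),
               sum(dgamma(as.numeric(th)[-1], shape = pr$shape[-1],
                          scale = pr$scale[-1], log = TRUE)),
               tolerance = 1e-12)
})

test_that("g1 marginal log density peaks at the Gamma mode", {
  pr <- erp_priors()
  grid <- seq(1e-4, 3, length.out = 200001)   # fine-grid search oracle
  dens <- dgamma(grid, shape = 18.16, scale = 0.03, log = TRUE)
  mode_grid <- grid[which.max(dens)]
  expect_equal(mode_grid, (18.16 - 1) * 0.03, tolerance = 1e-4)
  expect_equal((18.16 - 1) * 0.03, 0.5148)
})

test_that("tail sampling lands outside the central prior interval", {
  pr <- erp_priors()
  set.seed(8)
  draws <- sample_prior_tails(pr, tail_mass = 0.025, n = 200)
  for (j in seq_len(ncol(draws))) {
    u <- pgamma(draws[, j], shape = pr$shape[j], scale = pr$scale[j])
    expect_true(all(u <= 0.025 + 1e-10 | u >= 0.975 - 1e-10))
  }
  # tail_mass -> 0.5 degenerates to covering the whole support
  wide <- sample_prior_tails(pr, tail_mass = 0.4999, n = 500)
  u1 <- pgamma(wide[, 1], shape = pr$shape[1], scale = pr$scale[1])
  expect_gt(diff(range(u1)), 0.9)
})

test_that("prior files round-trip through YAML and JSON", {
  pr <- erp_priors()
  for (ext in c(".yaml", ".json")) {
    f <- tempfile(fileext = ext)
    write_priors(pr, f)
    back <- read_priors(f)
    expect_equal(back$shape, pr$shape)
    expect_equal(back$scale, pr$scale)
  }
})

test_that("pointwise likelihood matches the closed-form Gaussian density", {
  clean_obs <- generate_observation(seed = 1, sigma_obs = 0)
  m <- erp_model(clean_obs, sigma_obs = 0.1)
  pw <- pointwise_loglik(m, nmm_params())
  expect_length(pw, 201)
  const <- log(1 / (sqrt(2 * pi) * 0.1))
  expect_equal(const, 1.38364, tolerance = 1e-5)
  expect_equal(pw, rep(const, 201), tolerance = 1e-10)
  # one residual of exactly one sd
  shifted <- clean_obs
  shifted$y[10] <- shifted$y[10] + 0.1
  m2 <- erp_model(shifted, sigma_obs = 0.1)
  pw2 <- pointwise_loglik(m2, nmm_params())
  expect_equal(pw2[10], const - 0.5, tolerance = 1e-10)
  expect_equal(pw2[-10], pw[-10], tolerance = 1e-12)
})

test_that("log joint adds prior and likelihood and is -Inf off-support or unstable", {
  m <- study_model()
  th <- nmm_params()
  expect_equal(log_joint(m, th),
               log_prior(th, m$priors) + sum(pointwise_loglik(m, th)),
               tolerance = 1e-10)
  expect_identical(log_joint(m, as_nmm_params(nmm_params(h_e = 1e4))), -Inf)
  bad <- as.numeric(th); bad[2] <- -1
  expect_identical(log_joint(m, bad), -Inf)
})

test_that("unconstrained transform is a bijection with the documented Jacobian", {
  m <- study_model()
  th <- nmm_params()
  z <- to_unconstrained(m, th)
  back <- from_unconstrained(m, z)
  expect_equal(as.numeric(back), as.numeric(th), tolerance = 1e-12)
  expect_equal(as.numeric(from_unconstrained(m, rep(0, 10))), rep(1, 10))
  # change of variables: unconstrained density = constrained + sum(zeta)
  r <- erpdcm:::log_post_unconstrained(m, z, grad = FALSE)
  expect_equal(r$value, log_joint(m, th) + sum(z), tolerance = 1e-8)
})

test_that("one-dimensional change of variables integrates to one under the log map", {
  # g1 marginal: Gamma density in theta vs transformed density in zeta = log theta
  sh <- 18.16; sc <- 0.03
  f_con <- function(t) dgamma(t, shape = sh, scale = sc)
  f_unc <- function(z) dgamma(exp(z), shape = sh, scale = sc) * exp(z)
  expect_equal(integrate(f_con, 0, Inf)$value, 1, tolerance = 1e-6)
  expect_equal(integrate(f_unc, -20, 5)$value, 1, tolerance = 1e-6)
})

test_that("analytic gradient of the unconstrained log joint matches finite differences", {
  m <- study_model()
  set.seed(9)
  # a stable perturbed point near the truth
  z <- log(as.numeric(nmm_params()) * exp(rnorm(10, 0, 0.02)))
  r <- erpdcm:::log_post_unconstrained(m, z)
  h <- 1e-6
  fd <- vapply(seq_along(z), function(j) {
    zp <- z; zm <- z
    zp[j] <- zp[j] + h; zm[j] <- zm[j] - h
    (erpdcm:::log_post_unconstrained(m, zp, grad = FALSE)$value -
     erpdcm:::log_post_unconstrained(m, zm, grad = FALSE)$value) / (2 * h)
  }, 0)
  expect_equal(r$grad, fd, tolerance = 1e-3)
})

test_that("reduced models drop the gain from the sampled vector", {
  m <- study_model()
  r1 <- reduced_model(m, "g1")
  expect_equal(sum(r1$free), 9)
  expect_identical(reduced_model(r1, "g1")$reduced, "g1")   # idempotent
  expect_error(reduced_model(m, "delta"), "g1")
  # forward simulation of the g1 = 0 model from the remaining truth is stable
  th0 <- nmm_params(g1 = 0)
  expect_true(simulate_nmm(th0, duration = 200)$stable)
  expect_identical(classify_dynamics(th0), "stable")
  # unconstrained dimension bookkeeping
  expect_length(to_unconstrained(r1, th0), 9)
})
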