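# Variational engines: Gaussian-target recovery, mean-field variance
# deficit, Laplace evidence oracle.

test_that("full-rank guide recovers a correlated Gaussian target", {
  # target: N(mu*, Sigma*) with strong correlation
  mu_star <- c(1, -2)
  Sig <- matrix(c(1, 0.8, 0.8, 1), 2)
  P <- solve(Sig)
  lp <- function(z) {
    d <- z - mu_star
    list(value = -0.5 * sum(d * (P %*% d)), grad = -as.numeric(P %*% d))
  }
  set.seed(1)
  core <- advi_core(lp, c(0, 0), full_rank = TRUE, n_iters = 20000,
                    learning_rate = 5e-3, sd0 = 0.3)
  expect_equal(core$mu, mu_star, tolerance = 0.1)
  fitted_cov <- core$L %*% t(core$L)
  expect_equal(fitted_cov[1, 2] / sqrt(fitted_cov[1, 1] * fitted_cov[2, 2]),
               0.8, tolerance = 0.1)
  expect_equal(core$sd, c(1, 1), tolerance = 0.15)
})

test_that("mean-field guide underestimates marginal sds on a correlated target", {
  mu_star <- c(0, 0)
  Sig <- matrix(c(1, 0.9, 0.9, 1), 2)
  P <- solve(Sig)
  lp <- function(z) list(value = -0.5 * sum(z * (P %*% z)),
                         grad = -as.numeric(P %*% z))
  set.seed(2)
  core <- advi_core(lp, c(0.5, 0.5), full_rank = FALSE, n_iters = 20000,
                    learning_rate = 5e-3, sd0 = 0.3)
  # exact mean-field solution has sd 1/sqrt(P_kk) = sqrt(1 - rho^2) < 1
  expect_true(all(core$sd <= 1))
  expect_equal(core$sd, rep(sqrt(1 - 0.9^2), 2), tolerance = 0.1)
})

test_that("Laplace evidence equals the closed-form marginal likelihood on a conjugate model", {
  set.seed(4)
  toy <- conjugate_toy(rnorm(5, 0.7, 1), mu0 = 0.2, tau0 = 1.3, sigma = 1)
  core <- laplace_core(toy$lp_fun, list(0))
  expect_equal(core$mu, toy$post_mean, tolerance = 1e-6)
  expect_equal(sqrt(core$sigma[1, 1]), toy$post_sd, tolerance = 1e-5)
  # quadratic log joint: Laplace evidence is exact
  expect_equal(core$elbo_laplace, toy$log_evidence, tolerance = 1e-6)
})

test_that("exactly Gaussian log joint is recovered to optimizer tolerance", {
  mu_star <- c(2, -1, 0.5)
  P <- diag(c(4, 1, 0.25))
  lp <- function(z) {
    d <- z - mu_star
    list(value = -0.5 * sum(d * (P %*% d)), grad = -as.numeric(P %*% d))
  }
  core <- laplace_core(lp, list(c(0, 0, 0)))
  expect_equal(core$mu, mu_star, tolerance = 1e-6)
  expect_equal(core$sigma, solve(P), tolerance = 1e-4)
})

test_that("unconstrained dimension enters the Laplace evidence bookkeeping", {
  m <- study_model()
  r1 <- reduced_model(m, "g2")
  expect_equal(sum(m$free) - sum(r1$free), 1)
})

test_that("ADVI on the ERP model yields a non-decreasing smoothed ELBO trace", {
  m <- study_model()
  cfg <- vi_config("mean_field", n_iters = 4000, learning_rate = 2e-3,
                   n_chains = 1, n_samples = 50, seed = 3,
                   init_strategy = "prior_tails")
  s <- run_advi(m, cfg)
  tr <- s$elbo_trace
  win <- sapply(split(tr, ceiling(seq_along(tr) / 1000)), function(w)
    mean(w[is.finite(w)]))
  expect_true(all(diff(win) > -abs(win[1]) * 0.01))
  expect_true(is.finite(s$free_energy))
  expect_equal(dim(s$draws), c(1, 50, 10))
})

test_that("Laplace and NUTS posterior means agree on the ERP model", {
  m <- study_model()
  s_nuts <- small_nuts_fit()
  s_lap <- run_laplace(m, vi_config("laplace", n_chains = 1, n_samples = 200,
                                    n_restarts = 4, seed = 6))
  mu_n <- colMeans(flat_draws_test(s_nuts))
  sd_n <- apply(flat_draws_test(s_nuts), 2, sd)
  mu_l <- colMeans(flat_draws_test(s_lap))
  expect_true(all(abs(mu_n - mu_l) < 2 * sd_n))
})
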