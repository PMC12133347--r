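# Convergence diagnostics against direct-formula and simulation oracles.

test_that("split R-hat is near 1 for i.i.d. chains and large for separated chains", {
  set.seed(1)
  m <- matrix(rnorm(4 * 1000), 4, 1000)
  expect_true(split_rhat(m) >= 0.99 && split_rhat(m) <= 1.02)
  m2 <- rbind(rnorm(500, 0), rnorm(500, 5))
  expect_gt(split_rhat(m2), 1.1)
})

test_that("split R-hat matches a step-by-step between/within calculation on a toy array", {
  m <- matrix(c(1, 2, 3, 4,
                2, 4, 6, 9), 2, 4, byrow = TRUE)
  # independent oracle: split, fractional-rank normalize, B/W formula
  sp <- rbind(m[, 1:2], m[, 3:4])
  r <- rank(as.vector(sp))
  zs <- matrix(qnorm((r - 3/8) / (length(r) + 1/4)), 4, 2)
  n <- 2
  W <- mean(apply(zs, 1, var))
  B <- n * var(rowMeans(zs))
  expected <- sqrt(((n - 1) / n * W + B / n) / W)
  expect_equal(split_rhat(m), expected, tolerance = 1e-12)
})

test_that("constant chains yield NaN diagnostics with a warning", {
  m <- matrix(1, 2, 20)
  expect_warning(r <- split_rhat(m), "constant")
  expect_true(is.nan(r))
  expect_warning(e <- ess_bulk(m), "constant")
  expect_true(is.nan(e))
  expect_warning(et <- ess_tail(m), "constant")
  expect_true(is.nan(et))
})

test_that("ESS of i.i.d. draws is close to the number of draws", {
  set.seed(2)
  m <- matrix(rnorm(4 * 500), 4, 500)
  total <- length(m)
  expect_true(ess_bulk(m) / total > 0.8 && ess_bulk(m) / total < 1.3)
  expect_true(ess_tail(m) / total > 0.5 && ess_tail(m) / total < 1.5)
})

test_that("ESS of an AR(1) chain matches the analytic efficiency within a factor of two", {
  set.seed(3)
  phi <- 0.9
  C <- 4; n <- 2000
  m <- t(vapply(seq_len(C), function(c)
    as.numeric(arima.sim(list(ar = phi), n)), numeric(n)))
  eff <- ess_bulk(m) / length(m)
  analytic <- (1 - phi) / (1 + phi)
  expect_equal(analytic, 0.0526, tolerance = 1e-3)
  expect_true(eff > analytic / 2 && eff < analytic * 2)
})

test_that("z-scores follow their definition on constructed samples", {
  set.seed(4)
  arr <- array(rnorm(2 * 100 * 2, mean = c(1, 2), sd = 1), c(2, 100, 2))
  # fill deterministically: parameter 1 centred at truth, parameter 2 offset
  arr[, , 1] <- 1 + 0.5 * array(rnorm(200), c(2, 100))
  arr[, , 2] <- 2 + 0.5 + 0.5 * array(rnorm(200), c(2, 100))
  dimnames(arr) <- list(NULL, NULL, c("g1", "g2"))
  s <- samples_from_array(arr)
  z <- z_scores(s, truth = c(g1 = 1, g2 = 2))
  fl <- flat_draws_test(s)
  expect_equal(unname(z[1]), (mean(fl[, 1]) - 1) / sd(fl[, 1]), tolerance = 1e-12)
  expect_equal(unname(z[2]), (mean(fl[, 2]) - 2) / sd(fl[, 2]), tolerance = 1e-12)
  # exact centring gives 0, one-sd offset gives 1
  arr[, , 1] <- sweep(arr[, , 1, drop = FALSE], 3, mean(arr[, , 1]) - 1)[, , 1]
  s0 <- samples_from_array(arr)
  expect_equal(unname(z_scores(s0, c(g1 = 1, g2 = 2))[1]), 0, tolerance = 1e-10)
  # degenerate posterior errors
  arr[, , 1] <- 1
  expect_error(z_scores(samples_from_array(arr), c(g1 = 1, g2 = 2)),
               "degenerate")
})

test_that("fit RMSE follows its definition and detects pure noise", {
  m <- study_model()
  # posterior concentrated exactly at the truth
  arr <- array(rep(as.numeric(nmm_params()), each = 2 * 50), c(2, 50, 10))
  arr <- arr + array(rnorm(length(arr), 0, 1e-9), dim(arr))
  dimnames(arr) <- list(NULL, NULL, names(nmm_params()))
  s <- samples_from_array(arr)
  expect_equal(rmse_params(s, nmm_params()), 0, tolerance = 1e-6)
  # rmse_fit at the truth equals the noise RMS, close to sigma = 0.1
  rf <- rmse_fit(s, m)
  # sampling sd of the RMS of 201 N(0, 0.1) residuals is ~0.005
  expect_equal(rf, 0.1, tolerance = 0.15)
  # prediction equal to data -> rmse 0 (noise-free observation)
  clean <- generate_observation(seed = 2, sigma_obs = 0)
  m0 <- erp_model(clean)
  expect_equal(rmse_fit(s, m0), 0, tolerance = 1e-6)
})

test_that("diagnostic panel labels faithful fits by the 0.25 threshold", {
  s <- small_nuts_fit()
  m <- study_model()
  d <- fit_diagnostics(s, m)
  expect_identical(d$faithful, d$rmse_fit <= 0.25)
  expect_length(d$r_hat, 10)
  expect_true(all(d$ess_bulk > 0))
  expect_true(all(d$rel_ess_bulk <= 1.5))
  f <- tempfile(fileext = ".csv")
  tab <- write_diagnostics(list(nuts = d), f)
  expect_true(file.exists(f))
  expect_equal(nrow(tab), 1)
})
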