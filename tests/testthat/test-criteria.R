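# Information criteria: AIC/BIC arithmetic, WAIC brute-force equivalence,
# PSIS-LOO against exact leave-one-out on a conjugate model.

test_that("AIC and BIC follow their definitions", {
  expect_equal(aic(0, 0), 0)
  expect_equal(aic(-10, 10), 40)
  expect_equal(bic(-10, 10, 201), 20 + 10 * log(201))
  expect_equal(20 + 10 * log(201), 73.034, tolerance = 1e-3)
})

test_that("WAIC has zero penalty for identical draws and the exact identity holds", {
  ll <- matrix(rep(c(-1.2, -0.4, -2.2), each = 5), 5, 3)
  w <- waic(ll)
  expect_equal(w$p_waic, 0)
  expect_equal(w$waic, -2 * sum(ll[1, ]))
  expect_equal(w$waic, -2 * (w$lpd_hat - w$p_waic))
})

test_that("WAIC equals direct brute-force summation on small matrices", {
  brute <- function(ll) {
    S <- nrow(ll)
    lpd <- sum(log(colMeans(exp(ll))))
    p <- sum(apply(ll, 2, var))
    c(lpd = lpd, p = p, waic = -2 * (lpd - p))
  }
  set.seed(5)
  for (S in 2:3) for (n in 1:3) {
    ll <- matrix(rnorm(S * n, -1, 0.5), S, n)
    w <- waic(ll)
    b <- brute(ll)
    expect_equal(w$lpd_hat, unname(b["lpd"]), tolerance = 1e-10)
    expect_equal(w$p_waic, unname(b["p"]), tolerance = 1e-10)
    expect_equal(w$waic, unname(b["waic"]), tolerance = 1e-10)
  }
})

test_that("adding a constant shifts lpd_hat and leaves p_waic unchanged", {
  set.seed(6)
  ll <- matrix(rnorm(40, -1), 8, 5)
  w0 <- waic(ll)
  w1 <- waic(ll + 3)
  expect_equal(w1$lpd_hat, w0$lpd_hat + 5 * 3, tolerance = 1e-9)
  expect_equal(w1$p_waic, w0$p_waic, tolerance = 1e-9)
})

test_that("single-draw WAIC warns and sets the penalty to zero", {
  expect_warning(w <- waic(matrix(c(-1, -2), 1, 2)), "single draw")
  expect_equal(w$p_waic, 0)
})

test_that("PSIS-LOO degenerates correctly for identical draws", {
  ll <- matrix(rep(c(-1.5, -0.7), each = 20), 20, 2)
  l <- psis_loo(ll)
  expect_equal(l$elpd_psis_loo, -2 * sum(ll[1, ]), tolerance = 1e-9)
})

test_that("PSIS-LOO matches exact leave-one-out refits on a conjugate model", {
  set.seed(7)
  y <- rnorm(5, 0.8, 1)
  toy <- conjugate_toy(y)
  S <- 4000
  draws <- rnorm(S, toy$post_mean, toy$post_sd)
  ll <- vapply(seq_along(y), function(i) dnorm(y[i], draws, 1, log = TRUE),
               numeric(S))
  # exact LOO: analytic posterior refits without observation i
  exact <- vapply(seq_along(y), function(i) {
    t2 <- conjugate_toy(y[-i])
    # predictive density of y_i under posterior given y_{-i}
    dnorm(y[i], t2$post_mean, sqrt(t2$post_sd^2 + 1), log = TRUE)
  }, 0)
  l <- psis_loo(ll)
  expect_equal(l$pointwise, exact, tolerance = 0.02)
  expect_equal(l$elpd_psis_loo, -2 * sum(exact), tolerance = 0.1)
  expect_true(all(l$pareto_k < 0.7))
})

test_that("WAIC and PSIS-LOO agree on a well-specified fit", {
  s <- small_nuts_fit()
  pw <- flat_pointwise_test(s)
  w <- waic(pw)
  l <- psis_loo(pw)
  expect_lt(abs(l$elpd_psis_loo - w$waic), 0.05 * abs(w$waic))
})

test_that("model scores rank a dominated score set correctly", {
  s <- small_nuts_fit()
  m <- study_model()
  sc <- comparison_scores(s, m)
  expect_equal(sc$k, 10)
  expect_equal(sc$n, 201)
  expect_equal(sc$waic, -2 * (sc$lpd_hat - sc$p_waic), tolerance = 1e-9)
  expect_gte(sc$p_waic, 0)
  # two artificial score sets: shifting one criterion moves only that rank
  sc2 <- sc
  sc2$waic <- sc$waic + 100
  tab <- compare_models(list(a = sc, b = sc2),
                        criteria = c("aic", "waic"))
  expect_equal(tab$rank_waic[tab$model == "a"], 1)
  expect_equal(tab$rank_waic[tab$model == "b"], 2)
  expect_equal(tab$rank_aic, c(1, 1))   # tied on untouched criterion
  # identical score sets tie everywhere
  tab0 <- compare_models(list(a = sc, b = sc), criteria = c("waic"))
  expect_equal(tab0$rank_waic, c(1, 1))
})

test_that("likelihood optimization reaches at least the best posterior draw", {
  s <- small_nuts_fit()
  m <- study_model()
  mle <- erpdcm:::likelihood_mle(m, s)
  expect_gte(mle$max_loglik, max(s$stats$loglik) - 1e-6)
})
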