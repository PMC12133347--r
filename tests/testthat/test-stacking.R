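# Stacking weights, pooling, and mixture resampling.

test_that("single member receives weight one", {
  lpd <- matrix(rnorm(20, -1), 20, 1)
  r <- stacking_weights(lpd)
  expect_equal(unname(r$weights), 1, tolerance = 1e-8)
})

test_that("a pointwise-dominant member takes almost all weight, matching a grid oracle", {
  set.seed(1)
  n <- 50
  lpd <- cbind(a = rnorm(n, -1, 0.1),
               b = rnorm(n, -3, 0.1),
               c = rnorm(n, -4, 0.1))
  r <- stacking_weights(lpd)
  expect_gt(r$weights[["a"]], 0.99)
  # dense grid over the 2-simplex as oracle for the optimum objective
  g <- seq(0, 1, by = 0.02)
  best <- -Inf
  for (w1 in g) for (w2 in g[g <= 1 - w1 + 1e-12]) {
    w <- c(w1, w2, 1 - w1 - w2)
    if (any(w < 0)) next
    keep <- w > 0
    val <- mean(apply(lpd[, keep, drop = FALSE] +
                        matrix(log(w[keep]), n, sum(keep), byrow = TRUE),
                      1, function(row) {
                        mx <- max(row); mx + log(sum(exp(row - mx)))
                      }))
    if (val > best) best <- val
  }
  expect_gte(r$objective, best - 1e-6)
})

test_that("identical members tie toward uniform weights", {
  lpd_col <- rnorm(30, -1)
  r <- stacking_weights(cbind(lpd_col, lpd_col))
  expect_equal(unname(r$weights), c(0.5, 0.5), tolerance = 1e-3)
})

test_that("the optimum dominates every vertex and the uniform weighting", {
  set.seed(2)
  for (rep in 1:5) {
    K <- sample(2:4, 1)
    lpd <- matrix(rnorm(40 * K, -1, 0.7), 40, K)
    r <- stacking_weights(lpd)
    expect_true(all(r$weights >= -1e-10))
    expect_equal(sum(r$weights), 1, tolerance = 1e-8)
    for (k in seq_len(K)) {
      v <- numeric(K); v[k] <- 1
      expect_gte(r$objective,
                 erpdcm:::stacking_objective(lpd, v) - 1e-6)
    }
    expect_gte(r$objective,
               erpdcm:::stacking_objective(lpd, rep(1 / K, K)) - 1e-6)
  }
})

test_that("members with non-finite densities are dropped with a warning", {
  lpd <- cbind(rnorm(10, -1), c(-1, -Inf, rnorm(8, -1)))
  expect_warning(r <- stacking_weights(lpd), "dropped")
  expect_equal(unname(r$weights), c(1, 0), tolerance = 1e-8)
})

test_that("pooling concatenates chains and preserves means", {
  s <- small_nuts_fit()
  p <- pool_chains(s)
  expect_equal(n_chains(p), 1)
  expect_equal(n_draws(p), n_chains(s) * n_draws(s))
  expect_equal(colMeans(flat_draws_test(p)), colMeans(flat_draws_test(s)),
               tolerance = 1e-12)
  # single chain: pooling is the identity on the draws
  one <- erpdcm:::.chain_subset(s, 1)
  expect_equal(pool_chains(one)$draws[1, , ], one$draws[1, , ])
})

test_that("mixture resampling respects the weight vector", {
  s <- small_nuts_fit()
  # concentrated weights: output distribution equals that chain's draws
  conc <- structure(list(weights = c(1, 0), objective = 0,
                         member_pointwise = NULL),
                    class = "stacking_result")
  st <- stack_chains(s, conc, n_out = 300, seed = 2)
  expect_true(all(as.vector(st$draws[1, , 1]) %in% s$draws[1, , 1]))
  # multinomial representation within 4 sigma
  half <- structure(list(weights = c(0.3, 0.7), objective = 0,
                         member_pointwise = NULL),
                    class = "stacking_result")
  n_out <- 2000
  st2 <- stack_chains(s, half, n_out = n_out, seed = 3)
  from1 <- sum(as.vector(st2$draws[1, , 1]) %in% s$draws[1, , 1])
  expect_lt(abs(from1 - 0.3 * n_out), 4 * sqrt(n_out * 0.3 * 0.7))
  # reproducible
  st3 <- stack_chains(s, half, n_out = n_out, seed = 3)
  expect_identical(st2$draws, st3$draws)
})

test_that("stacking beats pooling when one member predicts poorly", {
  set.seed(4)
  n <- 100
  good <- rnorm(n, -0.9, 0.2)
  bad <- rnorm(n, -6, 0.5)
  lpd <- cbind(good = good, bad = bad)
  r <- stacking_weights(lpd)
  expect_gt(r$weights[["good"]], 0.95)
  pooled_obj <- erpdcm:::stacking_objective(lpd, c(0.5, 0.5))
  expect_gt(r$objective, pooled_obj)
})

test_that("stacking weights export as JSON", {
  r <- stacking_weights(matrix(rnorm(20, -1), 10, 2))
  f <- tempfile(fileext = ".json")
  write_stacking(r, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(sum(unlist(back$weights)), 1, tolerance = 1e-6)
})
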