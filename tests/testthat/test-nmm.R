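# Forward model: sigmoid, delay surrogate, right-hand side, Euler
# integration, stability classification.

test_that("firing-rate sigmoid has the exact closed form and odd shape", {
  expect_identical(nmm_sigmoid(0), 0)
  expect_equal(nmm_sigmoid(1), 1 / (1 + exp(-0.56)) - 0.5, tolerance = 1e-12)
  expect_equal(nmm_sigmoid(1e4), 0.5)
  expect_equal(nmm_sigmoid(-1e4), -0.5)
  v <- seq(-20, 20, length.out = 101)
  expect_true(all(diff(nmm_sigmoid(v)) > 0))          # strictly increasing
  expect_equal(nmm_sigmoid(-v), -nmm_sigmoid(v), tolerance = 1e-12)  # odd
  expect_true(all(abs(nmm_sigmoid(v)) < 0.5))
})

test_that("delay surrogate is closed-form and vanishes at zero delay", {
  th <- nmm_params()
  x <- c(5, 0, 0, 1, 2, 0.5, 3, 0.25, 7)
  th0 <- nmm_params(delta = 1e-300)   # effectively zero delay
  d0 <- nmm_delayed_state(x, th0)
  expect_equal(unname(d0), x[c(1, 7, 9)], tolerance = 1e-12)
  expect_equal(unname(nmm_delayed_state(rep(0, 9), th)), c(0, 0, 0))
  d <- nmm_delayed_state(x, nmm_params(delta = 12.13))
  expect_equal(unname(d[["x1"]]), 5 - 12.13 * 1)
  expect_equal(unname(d[["x7"]]), 3 - 12.13 * 0.25)
  expect_equal(unname(d[["x9"]]), 7 - 12.13 * (2 - 0.5))
})

test_that("origin is an equilibrium of the input-free system for any positive parameters", {
  set.seed(1)
  for (i in 1:20) {
    th <- as_nmm_params(exp(rnorm(10, 0, 1)))
    expect_equal(nmm_rhs(rep(0, 9), th, input_active = FALSE), rep(0, 9))
  }
})

test_that("step input at the origin drives only the stellate derivative state", {
  th <- nmm_params()
  f <- nmm_rhs(rep(0, 9), th, input_active = TRUE)
  expect_equal(f[4], th[["h_e"]] * th[["u"]] / th[["tau_e"]], tolerance = 1e-12)
  expect_equal(1.63 * 3.94 / 5.77, 1.11303, tolerance = 1e-5)
  expect_equal(f[-4], rep(0, 8))
})

test_that("delayed system with zero delay equals the instantaneous system", {
  # independent instantaneous-rhs oracle written directly from the equations
  naive_rhs <- function(x, th) {
    S <- function(v) 1 / (1 + exp(-0.56 * v)) - 0.5
    with(as.list(th), c(
      x[4], x[5], x[6],
      (h_e / tau_e) * (g1 * S(x[9]) + u) - x[1] / tau_e^2 - 2 * x[4] / tau_e,
      g2 * (h_e / tau_e) * S(x[1]) - x[2] / tau_e^2 - 2 * x[5] / tau_e,
      g4 * (h_i / tau_i) * S(x[7]) - x[3] / tau_i^2 - 2 * x[6] / tau_i,
      x[8],
      g3 * (h_e / tau_e) * S(x[9]) - x[7] / tau_e^2 - 2 * x[8] / tau_e,
      x[5] - x[6]))
  }
  th <- nmm_params(delta = 1e-300)
  set.seed(2)
  for (i in 1:10) {
    x <- rnorm(9)
    expect_equal(nmm_rhs(x, th, TRUE), naive_rhs(x, unclass(th)),
                 tolerance = 1e-10)
  }
})

test_that("Euler trajectory has the documented shape and preserves the equilibrium", {
  th <- nmm_params()
  tr <- simulate_nmm(th, duration = 200, dt = 0.1)
  expect_equal(length(tr$times), 2001)
  expect_equal(tr$times, seq(0, 200, by = 0.1))
  expect_true(tr$stable)
  tr0 <- simulate_nmm(th, duration = 10, input_active = FALSE)
  expect_true(all(tr0$states == 0))
  expect_error(simulate_nmm(th, dt = -0.1), "dt")
  expect_error(simulate_nmm(th, duration = 0), "duration")
})

test_that("Euler integration converges at first order on the pyramidal output", {
  th <- nmm_params()
  ref <- simulate_nmm(th, dt = 0.1 / 32, duration = 50)
  x9_ref <- ref$states[nrow(ref$states), "x9"]
  err <- vapply(c(0.1, 0.05, 0.025), function(dt) {
    tr <- simulate_nmm(th, dt = dt, duration = 50)
    abs(tr$states[nrow(tr$states), "x9"] - x9_ref)
  }, 0)
  ratios <- err[-length(err)] / err[-1]
  expect_true(all(ratios > 1.5 & ratios < 2.5))
})

test_that("trajectory stability classification flags blow-up and non-finite states", {
  tr <- simulate_nmm(nmm_params(), duration = 20)
  expect_identical(classify_stability(tr), "stable")
  tr$states[5, 3] <- NaN
  expect_identical(classify_stability(tr), "unstable")
  tr2 <- simulate_nmm(nmm_params(), duration = 20)
  tr2$states[7, 1] <- 2e3
  expect_identical(classify_stability(tr2), "unstable")
  # a huge synaptic amplitude genuinely exceeds the blow-up bound
  big <- nmm_params(h_e = 1e4)
  tr3 <- simulate_nmm(big, duration = 200)
  expect_false(tr3$stable)
  expect_identical(classify_stability(tr3), "unstable")
})

test_that("dynamical classifier separates settling from ringing parameter sets", {
  expect_identical(classify_dynamics(nmm_params()), "stable")
  expect_identical(classify_dynamics(nmm_params(g1 = 0)), "stable")
  # strong excitatory self-coupling with long delay rings indefinitely
  set.seed(4)
  draws <- sample_prior(n = 40)
  cls <- apply(draws, 1, classify_dynamics)
  expect_true(all(cls %in% c("stable", "unstable")))
  expect_true(any(cls == "unstable"))   # a visible fraction of prior mass rings
})

test_that("trajectory round-trips through the CSV exporter", {
  tr <- simulate_nmm(nmm_params(), duration = 5)
  f <- tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  dat <- read.csv(f)
  expect_identical(names(dat), c("time_ms", paste0("x", 1:9)))
  expect_equal(dat$x9, unname(tr$states[, "x9"]), tolerance = 1e-6)
})
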