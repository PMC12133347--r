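# No-U-Turn sampler with dual-averaging step-size adaptation and a diagonal
# mass-matrix warmup window, operating on an arbitrary differentiable
# unconstrained log density.

# lp_fun(z) must return list(value, grad, ...); extra fields (loglik,
# pointwise) are carried through to the recorded samples when present.

.leapfrog <- function(lp_fun, z, p, eps, m_inv, cache) {
  p <- p + 0.5 * eps * cache$grad
  z <- z + eps * m_inv * p
  cache <- lp_fun(z)
  p <- p + 0.5 * eps * cache$grad
  list(z = z, p = p, cache = cache)
}

.log_joint_zp <- function(cache, p, m_inv) cache$value - 0.5 * sum(m_inv * p * p)

# Recursive doubling of the slice-sampler NUTS tree (efficient variant).
.build_tree <- function(lp_fun, z, p, cache, log_u, v, j, eps, m_inv, z0_lj,
                        delta_max = 1000) {
  if (j == 0) {
    st <- .leapfrog(lp_fun, z, p, v * eps, m_inv, cache)
    lj <- .log_joint_zp(st$cache, st$p, m_inv)
    n_ok <- is.finite(lj) && log_u <= lj
    div <- !is.finite(lj) || (lj - log_u) < -delta_max
    list(z_minus = st$z, p_minus = st$p, cache_minus = st$cache,
         z_plus = st$z, p_plus = st$p, cache_plus = st$cache,
         z_prop = st$z, cache_prop = st$cache,
         n = as.integer(n_ok), s = !div, divergent = div,
         alpha = min(1, exp(min(0, lj - z0_lj))), n_alpha = 1L,
         n_leap = 1L)
  } else {
    t1 <- .build_tree(lp_fun, z, p, cache, log_u, v, j - 1, eps, m_inv, z0_lj,
                      delta_max)
    if (!t1$s) return(t1)
    if (v == -1) {
      t2 <- .build_tree(lp_fun, t1$z_minus, t1$p_minus, t1$cache_minus,
                        log_u, v, j - 1, eps, m_inv, z0_lj, delta_max)
      t1$z_minus <- t2$z_minus; t1$p_minus <- t2$p_minus
      t1$cache_minus <- t2$cache_minus
    } else {
      t2 <- .build_tree(lp_fun, t1$z_plus, t1$p_plus, t1$cache_plus,
                        log_u, v, j - 1, eps, m_inv, z0_lj, delta_max)
      t1$z_plus <- t2$z_plus; t1$p_plus <- t2$p_plus
      t1$cache_plus <- t2$cache_plus
    }
    n_tot <- t1$n + t2$n
    if (t2$n > 0 && runif(1) < t2$n / max(1, n_tot)) {
      t1$z_prop <- t2$z_prop; t1$cache_prop <- t2$cache_prop
    }
    dz <- t1$z_plus - t1$z_minus
    no_uturn <- sum(dz * (m_inv * t1$p_minus)) >= 0 &&
                sum(dz * (m_inv * t1$p_plus)) >= 0
    t1$n <- n_tot
    t1$s <- t2$s && no_uturn
    t1$divergent <- t1$divergent || t2$divergent
    t1$alpha <- t1$alpha + t2$alpha
    t1$n_alpha <- t1$n_alpha + t2$n_alpha
    t1$n_leap <- t1$n_leap + t2$n_leap
    t1
  }
}

.find_epsilon <- function(lp_fun, z, cache, m_inv) {
  eps <- 1
  p <- rnorm(length(z)) / sqrt(m_inv)
  lj0 <- .log_joint_zp(cache, p, m_inv)
  st <- .leapfrog(lp_fun, z, p, eps, m_inv, cache)
  lj <- .log_joint_zp(st$cache, st$p, m_inv)
  if (!is.finite(lj)) lj <- -Inf
  a <- if (lj - lj0 > log(0.5)) 1 else -1
  for (i in 1:50) {
    eps <- eps * 2^a
    st <- .leapfrog(lp_fun, z, p, eps, m_inv, cache)
    lj <- .log_joint_zp(st$cache, st$p, m_inv)
    if (!is.finite(lj)) lj <- -Inf
    if (a * (lj - lj0) <= a * log(0.5)) break
  }
  eps
}

# Single NUTS chain; init is the unconstrained starting point with a finite
# target value. Warmup: dual averaging throughout; the diagonal metric is
# (re-)estimated once at 70% of warmup from the draws of the preceding
# window, after which dual averaging restarts.
nuts_chain <- function(lp_fun, init, n_warmup, n_samples, max_tree_depth = 10,
                       target_accept = 0.8, delta_max = 1000) {
  k <- length(init)
  z <- init
  cache <- lp_fun(z)
  if (!is.finite(cache$value)) stop("initial point has non-finite log density")
  m_inv <- rep(1, k)

  total <- n_warmup + n_samples
  zs <- matrix(NA_real_, total, k)
  lp <- numeric(total); divergent <- logical(total)
  depth <- integer(total); stepsize <- numeric(total)
  extras <- vector("list", total)

  # dual averaging state
  eps <- .find_epsilon(lp_fun, z, cache, m_inv)
  da <- list(mu = log(10 * eps), log_eps_bar = 0, h_bar = 0, m = 0)
  gamma <- 0.05; t0 <- 10; kappa <- 0.75
  eps_bar <- eps

  # metric windows: (re-)estimate the diagonal metric from accumulated draws
  # at 50% and 80% of warmup (one window at 70% for short warmups), with the
  # remaining warmup reserved for step-size re-adaptation
  metric_at <- if (n_warmup >= 60) c(floor(0.5 * n_warmup), floor(0.8 * n_warmup))
               else if (n_warmup >= 40) floor(0.7 * n_warmup) else integer()
  window_start <- max(1, floor(0.1 * n_warmup))

  for (it in seq_len(total)) {
    p0 <- rnorm(k) / sqrt(m_inv)
    lj0 <- .log_joint_zp(cache, p0, m_inv)
    log_u <- lj0 + log(runif(1))
    tree <- list(z_minus = z, p_minus = p0, cache_minus = cache,
                 z_plus = z, p_plus = p0, cache_plus = cache,
                 z_prop = z, cache_prop = cache, n = 1L, s = TRUE,
                 divergent = FALSE, alpha = 0, n_alpha = 0L)
    j <- 0
    use_eps <- if (it <= n_warmup) eps else eps_bar
    while (tree$s && j < max_tree_depth) {
      v <- sample(c(-1, 1), 1)
      sub <- if (v == -1)
        .build_tree(lp_fun, tree$z_minus, tree$p_minus, tree$cache_minus,
                    log_u, v, j, use_eps, m_inv, lj0, delta_max)
      else
        .build_tree(lp_fun, tree$z_plus, tree$p_plus, tree$cache_plus,
                    log_u, v, j, use_eps, m_inv, lj0, delta_max)
      if (v == -1) {
        tree$z_minus <- sub$z_minus; tree$p_minus <- sub$p_minus
        tree$cache_minus <- sub$cache_minus
      } else {
        tree$z_plus <- sub$z_plus; tree$p_plus <- sub$p_plus
        tree$cache_plus <- sub$cache_plus
      }
      if (sub$s && sub$n > 0 && runif(1) < sub$n / max(1, tree$n)) {
        tree$z_prop <- sub$z_prop; tree$cache_prop <- sub$cache_prop
      }
      tree$n <- tree$n + sub$n
      dz <- tree$z_plus - tree$z_minus
      tree$s <- sub$s &&
        sum(dz * (m_inv * tree$p_minus)) >= 0 &&
        sum(dz * (m_inv * tree$p_plus)) >= 0
      tree$divergent <- tree$divergent || sub$divergent
      tree$alpha <- sub$alpha; tree$n_alpha <- sub$n_alpha
      j <- j + 1
    }
    z <- tree$z_prop; cache <- tree$cache_prop
    zs[it, ] <- z
    lp[it] <- cache$value
    divergent[it] <- tree$divergent
    depth[it] <- j
    stepsize[it] <- use_eps
    extras[[it]] <- cache

    if (it <= n_warmup) {
      a_stat <- if (tree$n_alpha > 0) tree$alpha / tree$n_alpha else 0
      da$m <- da$m + 1
      frac <- 1 / (da$m + t0)
      da$h_bar <- (1 - frac) * da$h_bar + frac * (target_accept - a_stat)
      log_eps <- da$mu - sqrt(da$m) / gamma * da$h_bar
      w <- da$m^(-kappa)
      da$log_eps_bar <- w * log_eps + (1 - w) * da$log_eps_bar
      eps <- exp(log_eps)
      eps_bar <- exp(da$log_eps_bar)
      if (it %in% metric_at) {
        win <- zs[window_start:it, , drop = FALSE]
        v_est <- apply(win, 2, var)
        n_w <- nrow(win)
        m_inv <- (n_w / (n_w + 5)) * v_est + (5 / (n_w + 5)) * 1e-3
        m_inv[!is.finite(m_inv) | m_inv <= 0] <- 1e-3
        eps <- .find_epsilon(lp_fun, z, cache, m_inv)
        da <- list(mu = log(10 * eps), log_eps_bar = 0, h_bar = 0, m = 0)
        eps_bar <- eps
        window_start <- it + 1
      }
    }
  }
  keep <- n_warmup + seq_len(n_samples)
  list(z = zs[keep, , drop = FALSE], lp = lp[keep],
       divergent = divergent[keep], depth = depth[keep],
       stepsize = stepsize[keep], caches = extras[keep],
       eps_final = eps_bar, m_inv = m_inv)
}

#' Sampler configuration
#'
#' Defaults follow the study's benchmark configuration: four chains, 200
#' warmup and 200 sampling iterations, maximum tree depth 10, target
#' acceptance 0.8.
#'
#' @param n_chains,n_warmup,n_samples chain count and iteration budget.
#' @param max_tree_depth maximum doubling depth (at most 2^depth leapfrog
#'   steps per iteration).
#' @param target_accept target Metropolis acceptance statistic in (0, 1).
#' @param init_strategy \code{"prior_tails"}, \code{"random"} (prior draws)
#'   or \code{"value"} (explicit \code{init_values}).
#' @param init_values optional matrix (chains x 10) of constrained starting
#'   points for \code{init_strategy = "value"}.
#' @param seed integer seed.
#' @export
sampler_config <- function(n_chains = 4, n_warmup = 200, n_samples = 200,
                           max_tree_depth = 10, target_accept = 0.8,
                           init_strategy = c("prior_tails", "random", "value"),
                           init_values = NULL, seed = 1) {
  stopifnot(max_tree_depth >= 1, target_accept > 0, target_accept < 1,
            n_chains >= 1, n_warmup >= 0, n_samples >= 1)
  list(n_chains = n_chains, n_warmup = n_warmup, n_samples = n_samples,
       max_tree_depth = max_tree_depth, target_accept = target_accept,
       init_strategy = match.arg(init_strategy), init_values = init_values,
       seed = seed)
}

# Draw a constrained initialization with finite log joint (resampling
# unstable draws, which have log density -Inf).
.init_point <- function(model, strategy, init_values, chain, max_tries = 200) {
  for (tr in seq_len(max_tries)) {
    theta <- switch(strategy,
      prior_tails = sample_prior_tails(model$priors)[1, ],
      random = sample_prior(model$priors)[1, ],
      value = init_values[chain, ])
    z <- log(theta[model$free])
    if (is.finite(log_post_unconstrained(model, z, grad = FALSE)$value))
      return(z)
    if (strategy == "value")
      stop("supplied initial value has non-finite log density for chain ", chain)
  }
  stop("failed to find a finite-density ", strategy,
       " initialization in ", max_tries, " tries")
}

#' Run the No-U-Turn sampler on an ERP model
#'
#' Self-tuning Hamiltonian Monte Carlo in unconstrained (log-parameter)
#' space: dynamic trajectory doubling bounded by \code{max_tree_depth},
#' dual-averaging step-size adaptation toward \code{target_accept}, and a
#' diagonal mass matrix estimated during warmup. Divergent transitions
#' (leapfrog energy error beyond 1000) are flagged per iteration. Draws are
#' returned in constrained space together with the per-draw pointwise
#' log-likelihood.
#'
#' @param model an \code{erp_model}.
#' @param config a \code{sampler_config}.
#' @return An \code{erp_samples} object; \code{stats} holds \code{lp}
#'   (unconstrained log density), \code{loglik}, \code{divergent},
#'   \code{tree_depth}, \code{step_size}.
#' @export
#' @examples
#' \donttest{
#' obs <- generate_observation(seed = 1)
#' m <- erp_model(obs)
#' fit <- run_nuts(m, sampler_config(n_chains = 2, n_warmup = 50,
#'                                   n_samples = 50, seed = 1))
#' summary(fit)
#' }
run_nuts <- function(model, config = sampler_config()) {
  stopifnot(inherits(model, "erp_model"))
  k <- sum(model$free)
  pn <- .param_names[model$free]
  N <- length(model$observation$y)
  C <- config$n_chains; S <- config$n_samples
  draws <- array(NA_real_, c(C, S, k), dimnames = list(NULL, NULL, pn))
  pw <- array(NA_real_, c(C, S, N))
  lp <- ll <- ss <- matrix(NA_real_, C, S)
  dv <- matrix(FALSE, C, S)
  td <- matrix(NA_integer_, C, S)
  lp_fun <- function(z) log_post_unconstrained(model, z)
  failed <- 0
  for (c in seq_len(C)) {
    set.seed(config$seed + 1000 * (c - 1))
    init <- tryCatch(.init_point(model, config$init_strategy,
                                 config$init_values, c),
                     error = identity)
    if (inherits(init, "error")) { failed <- failed + 1; next }
    ch <- nuts_chain(lp_fun, init, config$n_warmup, S,
                     config$max_tree_depth, config$target_accept)
    draws[c, , ] <- exp(ch$z)
    lp[c, ] <- ch$lp
    dv[c, ] <- ch$divergent
    td[c, ] <- ch$depth
    ss[c, ] <- ch$stepsize
    for (s in seq_len(S)) {
      pw[c, s, ] <- ch$caches[[s]]$pointwise
      ll[c, s] <- ch$caches[[s]]$loglik
    }
  }
  if (failed == C)
    stop("all chains failed at initialization (strategy: ",
         config$init_strategy, ")")
  if (failed > 0) {
    keep <- which(apply(draws, 1, function(a) all(is.finite(a))))
    draws <- draws[keep, , , drop = FALSE]; pw <- pw[keep, , , drop = FALSE]
    lp <- lp[keep, , drop = FALSE]; ll <- ll[keep, , drop = FALSE]
    dv <- dv[keep, , drop = FALSE]; td <- td[keep, , drop = FALSE]
    ss <- ss[keep, , drop = FALSE]
    warning(failed, " chain(s) dropped after failed initialization")
  }
  new_erp_samples(draws, pw,
                  list(lp = lp, loglik = ll, divergent = dv,
                       tree_depth = td, step_size = ss),
                  "nuts", extra = list(config = config))
}

#' Low-level NUTS on a user-supplied log density
#'
#' Runs the same sampler core as \code{\link{run_nuts}} on an arbitrary
#' differentiable log density, for testing and for toy targets.
#'
#' @param lp_fun function of the position vector returning
#'   \code{list(value, grad)}.
#' @param init numeric starting position (finite density).
#' @param n_warmup,n_samples,max_tree_depth,target_accept as in
#'   \code{\link{sampler_config}}.
#' @param seed integer seed.
#' @return List with \code{z} (draws matrix), \code{lp}, \code{divergent},
#'   \code{depth}, \code{stepsize}.
#' @export
nuts_sample <- function(lp_fun, init, n_warmup = 200, n_samples = 200,
                        max_tree_depth = 10, target_accept = 0.8, seed = 1) {
  set.seed(seed)
  nuts_chain(lp_fun, init, n_warmup, n_samples, max_tree_depth, target_accept)
}
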