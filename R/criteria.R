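# Information criteria and evidence approximations: AIC, BIC, WAIC,
# PSIS-LOO. All headline values are on the deviance scale (-2x, smaller is
# better); conventional positive elpd values are stored alongside.

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Akaike / Bayesian information criteria
#'
#' \code{aic = -2 max_loglik + 2k}; \code{bic = -2 max_loglik + k log(n)}.
#'
#' @param max_loglik maximized log likelihood.
#' @param k number of free parameters.
#' @param n number of observations (BIC only).
#' @export
aic <- function(max_loglik, k) {
  stopifnot(k >= 0)
  -2 * max_loglik + 2 * k
}

#' @rdname aic
#' @export
bic <- function(max_loglik, k, n) {
  stopifnot(k >= 0, n >= 1)
  -2 * max_loglik + k * log(n)
}

#' Widely applicable information criterion
#'
#' From an S x n pointwise log-likelihood matrix:
#' \code{lpd_hat = sum_i log mean_s exp(ll[s,i])} (computed stably),
#' \code{p_waic = sum_i var_s ll[s,i]}, and
#' \code{waic = -2 (lpd_hat - p_waic)}.
#'
#' @param pointwise S draws x n points matrix of pointwise log-likelihoods.
#' @return List with \code{lpd_hat}, \code{p_waic}, \code{waic},
#'   \code{elpd_waic} (= lpd_hat - p_waic) and per-point \code{pointwise}
#'   elpd contributions.
#' @export
waic <- function(pointwise) {
  m <- as.matrix(pointwise)
  S <- nrow(m)
  lpd_i <- apply(m, 2, function(col) .logsumexp(col) - log(S))
  if (S < 2) {
    warning("single draw: p_waic set to 0")
    p_i <- rep(0, ncol(m))
  } else {
    p_i <- apply(m, 2, var)
  }
  elpd_i <- lpd_i - p_i
  list(lpd_hat = sum(lpd_i), p_waic = sum(p_i),
       waic = -2 * (sum(lpd_i) - sum(p_i)),
       elpd_waic = sum(elpd_i), pointwise = elpd_i)
}

# Generalized Pareto fit to exceedances (profile-likelihood grid estimator).
# Returns shape k and scale sigma.
.gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior_bs <- 3 * x[max(1, floor(n / 4 + 0.5))]
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / prior_bs
  k_j <- vapply(theta, function(th) -mean(log1p(-th * x)), 0)
  l_j <- n * (log(theta / k_j) + k_j - 1)
  w <- 1 / vapply(seq_len(m), function(j) sum(exp(l_j - l_j[j])), 0)
  th_hat <- sum(theta * w)
  k_hat <- -mean(log1p(-th_hat * x))
  list(k = k_hat, sigma = k_hat / th_hat)
}

.qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log1p(-p) else sigma * expm1(-k * log1p(-p)) / k
}

# Pareto-smoothed importance-sampling log weights for one observation.
# lw: raw log importance ratios (length S). Returns smoothed lw and k-hat.
.psis_smooth <- function(lw, tail_min = 5) {
  S <- length(lw)
  # top 20% capped at 3*sqrt(S): an uncapped 20% tail visibly biases the
  # estimate against exact leave-one-out refits once S is large
  M <- max(tail_min, ceiling(min(0.2 * S, 3 * sqrt(S))))
  if (S <= M || S < 2 * tail_min) {
    return(list(lw = lw, khat = Inf, smoothed = FALSE))
  }
  ord <- order(lw)
  tail_idx <- ord[(S - M + 1):S]
  cutoff <- exp(lw[ord[S - M]] - max(lw))
  exc <- exp(lw[tail_idx] - max(lw)) - cutoff
  if (all(exc <= 0)) return(list(lw = lw, khat = NaN, smoothed = FALSE))
  fit <- .gpd_fit(exc[exc > 0])
  q <- .qgpd((seq_len(M) - 0.5) / M, fit$k, fit$sigma)
  sm <- log(cutoff + q) + max(lw)
  sm <- pmin(sm, max(lw))       # never exceed the largest raw weight
  lw[tail_idx[order(lw[tail_idx])]] <- sort(sm)
  list(lw = lw, khat = fit$k, smoothed = TRUE)
}

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' Per observation, the raw importance ratios for leaving that point out are
#' the reciprocals of its pointwise likelihoods across posterior draws. The
#' largest ratios (top 20\%, minimum 5) are replaced by expected order
#' statistics of a generalized Pareto distribution fitted to the tail, and
#' the leave-one-out predictive density is estimated by the self-normalized
#' weighted average. With too few draws for the tail fit, plain importance
#' sampling is used with a warning.
#'
#' @param pointwise S draws x n points matrix of pointwise log-likelihoods.
#' @return List with \code{elpd_psis_loo} (deviance scale, -2x), \code{elpd}
#'   (positive scale), per-point \code{pointwise} elpd, and per-point
#'   \code{pareto_k} shape diagnostics.
#' @export
psis_loo <- function(pointwise) {
  m <- as.matrix(pointwise)
  S <- nrow(m); n <- ncol(m)
  stopifnot(S >= 2)
  elpd_i <- numeric(n)
  khat <- numeric(n)
  warned <- FALSE
  for (i in seq_len(n)) {
    lw <- -m[, i]
    sm <- .psis_smooth(lw)
    if (!sm$smoothed && !warned && S < 10) {
      warning("too few draws for Pareto tail fit; using unsmoothed importance sampling")
      warned <- TRUE
    }
    lw_s <- sm$lw - .logsumexp(sm$lw)     # self-normalized
    elpd_i[i] <- .logsumexp(lw_s + m[, i])
    khat[i] <- sm$khat
  }
  list(elpd_psis_loo = -2 * sum(elpd_i), elpd = sum(elpd_i),
       pointwise = elpd_i, pareto_k = khat)
}

# Maximum-likelihood point: optimize the likelihood alone in unconstrained
# space, initialized from the posterior mean and the best posterior draw;
# the better optimum is kept.
likelihood_mle <- function(model, samples) {
  free <- model$free
  ll_only <- function(z, want_grad) {
    th <- full_theta(model, exp(z))
    r <- .nmm_loglik_grad_cpp(as.numeric(th), model$observation$y, model$dt,
                              model$n_steps, model$downsample,
                              model$sigma_obs, 1.0, model$blowup, want_grad)
    list(value = r$loglik, grad = as.numeric(r$grad)[free] * exp(z))
  }
  fn <- function(z) {
    v <- ll_only(z, FALSE)$value
    if (is.finite(v)) -v else 1e10
  }
  gr <- function(z) {
    r <- ll_only(z, TRUE)
    if (is.finite(r$value)) -r$grad else numeric(length(z))
  }
  fl <- flat_draws(samples)
  ll_flat <- as.vector(t(samples$stats$loglik))
  inits <- rbind(log(colMeans(fl)),
                 log(fl[which.max(ll_flat), ]))
  best <- NULL
  for (i in seq_len(nrow(inits))) {
    opt <- tryCatch(optim(inits[i, ], fn, gr, method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-12)),
                    error = identity)
    if (inherits(opt, "error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("likelihood optimization failed from all starts")
  list(max_loglik = -best$value, theta = full_theta(model, exp(best$par)))
}

#' Model comparison scores for one fitted model
#'
#' Computes AIC, BIC (likelihood maximized from the posterior), WAIC and
#' PSIS-LOO from the recorded pointwise log-likelihoods, and carries the
#' variational free energy when the engine recorded one. All criteria are on
#' the deviance scale: smaller indicates better predictive ability.
#'
#' @param samples an \code{erp_samples} object for the model.
#' @param model the fitted \code{erp_model}.
#' @return Object of class \code{comparison_scores}.
#' @export
comparison_scores <- function(samples, model) {
  pw <- flat_pointwise(samples)
  keep <- is.finite(rowSums(pw))
  pw <- pw[keep, , drop = FALSE]
  w <- waic(pw)
  loo <- psis_loo(pw)
  mle <- likelihood_mle(model, samples)
  k <- sum(model$free)
  n <- ncol(pw)
  structure(list(aic = aic(mle$max_loglik, k), bic = bic(mle$max_loglik, k, n),
                 max_loglik = mle$max_loglik, theta_mle = mle$theta,
                 lpd_hat = w$lpd_hat, p_waic = w$p_waic, waic = w$waic,
                 elpd_psis_loo = loo$elpd_psis_loo, elpd_loo = loo$elpd,
                 pareto_k = loo$pareto_k, loo_pointwise = loo$pointwise,
                 elbo = if (!is.null(samples$free_energy)) samples$free_energy
                        else NA_real_,
                 k = k, n = n, reduced = model$reduced),
            class = "comparison_scores")
}

#' @export
print.comparison_scores <- function(x, ...) {
  cat(sprintf("Model scores (k = %d, n = %d%s):\n", x$k, x$n,
              if (length(x$reduced)) paste0(", ", paste(x$reduced, collapse = ","),
                                            " = 0") else ""))
  cat(sprintf("  AIC %.1f | BIC %.1f | WAIC %.1f | PSIS-LOO %.1f | max k-hat %.2f\n",
              x$aic, x$bic, x$waic, x$elpd_psis_loo, max(x$pareto_k)))
  invisible(x)
}

#' Rank models by each criterion
#'
#' @param scores named list of \code{comparison_scores}, all computed on the
#'   same observation series.
#' @param criteria criteria columns to rank on.
#' @return Data frame, one row per model, with criterion values and ranks
#'   (1 = best, i.e. smallest) plus an attribute \code{agreement} flagging
#'   whether all criteria agree on the best and worst model.
#' @export
compare_models <- function(scores,
                           criteria = c("aic", "bic", "waic",
                                        "elpd_psis_loo", "elbo")) {
  stopifnot(length(scores) >= 2)
  ns <- vapply(scores, function(s) s$n, 0)
  if (length(unique(ns)) != 1)
    stop("models were scored on different numbers of observations")
  have <- criteria[vapply(criteria, function(cr)
    all(vapply(scores, function(s) is.finite(s[[cr]]), TRUE)), TRUE)]
  tab <- data.frame(model = names(scores),
                    k = vapply(scores, function(s) s$k, 0))
  for (cr in have) {
    v <- vapply(scores, function(s) s[[cr]], 0)
    tab[[cr]] <- v
    tab[[paste0("rank_", cr)]] <- rank(v, ties.method = "min")
  }
  best <- vapply(have, function(cr) tab$model[which.min(tab[[cr]])], "")
  worst <- vapply(have, function(cr) tab$model[which.max(tab[[cr]])], "")
  attr(tab, "agreement") <- list(
    best = best, worst = worst,
    best_agree = length(unique(best)) == 1,
    worst_agree = length(unique(worst)) == 1)
  tab[order(tab[[paste0("rank_", have[1])]]), ]
}
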