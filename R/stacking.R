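# Stacking of Bayesian predictive distributions: simplex weights maximizing
# the leave-one-out predictive density, applied to chains or models.

#' Stacking weights over predictive distributions
#'
#' Given per-member leave-one-out pointwise log predictive densities
#' (typically PSIS-LOO estimates of \eqn{\log p(y_i | y_{-i}, M_k)}), finds
#' simplex weights maximizing the average log mixture predictive density
#' \deqn{\frac1n \sum_i \log \sum_k w_k \, p(y_i \mid y_{-i}, M_k).}
#' The optimization uses a softmax reparametrization with multiple starts
#' (the objective is concave in \code{w}, so starts only guard the
#' reparametrized landscape) and an L2 ridge of 1e-8 pulling toward uniform
#' weights, which breaks ties between identical members.
#'
#' @param lpd_matrix n points x K members matrix of pointwise log predictive
#'   densities. Members containing non-finite values are dropped with a
#'   warning.
#' @return Object of class \code{stacking_result}: \code{weights} (length K,
#'   zeros for dropped members), \code{objective} (achieved criterion),
#'   \code{member_elpds} (per-member sums), \code{member_pointwise}.
#' @export
stacking_weights <- function(lpd_matrix) {
  m <- as.matrix(lpd_matrix)
  K <- ncol(m)
  labels <- colnames(m)
  ok <- apply(m, 2, function(col) all(is.finite(col)))
  if (!all(ok)) {
    warning(sum(!ok), " member(s) with non-finite predictive density dropped")
    m <- m[, ok, drop = FALSE]
  }
  Ke <- ncol(m)
  if (Ke == 0) stop("no member with finite predictive densities")
  n <- nrow(m)
  obj <- function(a) {         # a: softmax logits (length Ke)
    a <- a - max(a)
    w <- exp(a) / sum(exp(a))
    mix <- apply(m + matrix(log(w), n, Ke, byrow = TRUE), 1, .logsumexp)
    mean(mix) - 1e-8 * sum((w - 1 / Ke)^2)
  }
  grad <- function(a) {
    a <- a - max(a)
    w <- exp(a) / sum(exp(a))
    lw <- matrix(log(w), n, Ke, byrow = TRUE)
    mix <- apply(m + lw, 1, .logsumexp)
    r <- exp(m + lw - mix)                    # n x Ke responsibilities
    dw <- colMeans(r) / w - 2e-8 * (w - 1 / Ke)
    # softmax Jacobian
    as.numeric(w * (dw - sum(dw * w)))
  }
  best <- NULL
  starts <- rbind(rep(0, Ke), diag(3, Ke), -diag(3, Ke))
  for (i in seq_len(nrow(starts))) {
    o <- tryCatch(optim(starts[i, ], function(a) -obj(a),
                        function(a) -grad(a), method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-12)),
                  error = identity)
    if (inherits(o, "error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  a <- best$par - max(best$par)
  w_eff <- exp(a) / sum(exp(a))
  w <- numeric(K)
  w[ok] <- w_eff
  names(w) <- labels
  mix <- apply(m + matrix(log(w_eff), n, Ke, byrow = TRUE), 1, .logsumexp)
  structure(list(weights = w, objective = mean(mix),
                 member_elpds = colSums(m), member_pointwise = m,
                 kept = ok),
            class = "stacking_result")
}

#' @export
print.stacking_result <- function(x, ...) {
  cat("Stacking weights:\n")
  print(round(x$weights, 4))
  cat(sprintf("objective (mean log predictive density): %.4f\n", x$objective))
  invisible(x)
}

# Objective of an arbitrary weight vector on a member-lpd matrix (used to
# certify optimizer dominance over vertex/uniform weightings).
stacking_objective <- function(lpd_matrix, w) {
  m <- as.matrix(lpd_matrix)
  keep <- w > 0
  mean(apply(m[, keep, drop = FALSE] +
               matrix(log(w[keep]), nrow(m), sum(keep), byrow = TRUE),
             1, .logsumexp))
}

#' Chain-level stacking of posterior samples
#'
#' Computes PSIS-LOO pointwise predictive densities per chain, solves for
#' stacking weights, and resamples a weighted mixture: each output draw
#' picks a chain with probability proportional to its weight, then a draw
#' uniformly within the chain.
#'
#' @param samples a multi-chain \code{erp_samples} object.
#' @return \code{stack_weights_chains}: a \code{stacking_result} with one
#'   member per chain.
#' @export
stack_weights_chains <- function(samples) {
  C <- n_chains(samples)
  lpd <- vapply(seq_len(C), function(c)
    psis_loo(samples$pointwise[c, , , drop = TRUE])$pointwise,
    numeric(dim(samples$pointwise)[3]))
  colnames(lpd) <- paste0("chain", seq_len(C))
  stacking_weights(lpd)
}

#' @rdname stack_weights_chains
#' @param result a \code{stacking_result} over the chains.
#' @param n_out number of mixture draws to produce.
#' @param seed integer seed (mixture resampling is stochastic).
#' @return \code{stack_chains}: a single-chain \code{erp_samples} holding the
#'   weighted mixture draws.
#' @export
stack_chains <- function(samples, result = stack_weights_chains(samples),
                         n_out = n_chains(samples) * n_draws(samples),
                         seed = 1) {
  set.seed(seed)
  C <- n_chains(samples); S <- n_draws(samples)
  w <- result$weights
  stopifnot(length(w) == C)
  chain_pick <- sample.int(C, n_out, replace = TRUE, prob = w)
  draw_pick <- sample.int(S, n_out, replace = TRUE)
  k <- dim(samples$draws)[3]; N <- dim(samples$pointwise)[3]
  draws <- array(NA_real_, c(1, n_out, k),
                 dimnames = list(NULL, NULL, samples$param_names))
  pw <- array(NA_real_, c(1, n_out, N))
  for (i in seq_len(n_out)) {
    draws[1, i, ] <- samples$draws[chain_pick[i], draw_pick[i], ]
    pw[1, i, ] <- samples$pointwise[chain_pick[i], draw_pick[i], ]
  }
  new_erp_samples(draws, pw, list(), paste0(samples$method, "+stacked"),
                  extra = list(stacking = result))
}

#' Export stacking weights as JSON
#' @param result a \code{stacking_result}.
#' @param path output path.
#' @export
write_stacking <- function(result, path) {
  jsonlite::write_json(list(weights = as.list(result$weights),
                            objective = result$objective),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
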