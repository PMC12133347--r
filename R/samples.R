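# Posterior sample container shared by every inference engine.

# draws: chains x iterations x parameters (constrained space)
# pointwise: chains x iterations x N pointwise log-likelihood
# stats: list of chains x iterations matrices (lp, loglik, divergent,
#        tree_depth, step_size, energy as available)
new_erp_samples <- function(draws, pointwise, stats, method,
                            param_names = dimnames(draws)[[3]],
                            extra = list()) {
  stopifnot(length(dim(draws)) == 3, length(dim(pointwise)) == 3)
  obj <- c(list(draws = draws, pointwise = pointwise, stats = stats,
                method = method, param_names = param_names), extra)
  class(obj) <- "erp_samples"
  obj
}

#' @export
print.erp_samples <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("Posterior samples (%s): %d chains x %d draws x %d parameters\n",
              x$method, d[1], d[2], d[3]))
  if (!is.null(x$stats$divergent))
    cat(sprintf("  divergent transitions: %d\n", sum(x$stats$divergent)))
  invisible(x)
}

#' Number of chains / draws in a sample object
#' @param samples an \code{erp_samples} object.
#' @export
n_chains <- function(samples) dim(samples$draws)[1]

#' @rdname n_chains
#' @export
n_draws <- function(samples) dim(samples$draws)[2]

# All draws flattened to a (chains*iterations) x parameters matrix.
flat_draws <- function(samples) {
  d <- dim(samples$draws)
  m <- matrix(aperm(samples$draws, c(2, 1, 3)), d[1] * d[2], d[3])
  colnames(m) <- samples$param_names
  m
}

# Flattened pointwise log-likelihood, (chains*iterations) x N.
flat_pointwise <- function(samples) {
  d <- dim(samples$pointwise)
  matrix(aperm(samples$pointwise, c(2, 1, 3)), d[1] * d[2], d[3])
}

#' Posterior summary table
#'
#' Per-parameter posterior mean, sd and quantiles over all chains.
#'
#' @param object an \code{erp_samples} object.
#' @param probs quantiles to report.
#' @param ... unused.
#' @export
summary.erp_samples <- function(object, probs = c(0.025, 0.5, 0.975), ...) {
  m <- flat_draws(object)
  out <- data.frame(parameter = colnames(m), mean = colMeans(m),
                    sd = apply(m, 2, sd))
  q <- t(apply(m, 2, quantile, probs = probs))
  colnames(q) <- paste0("q", probs * 100)
  out <- cbind(out, q)
  rownames(out) <- NULL
  out
}

#' Posterior mean of the full parameter vector
#'
#' @param samples an \code{erp_samples} object.
#' @param model optionally, the \code{erp_model}; when given, masked
#'   (reduced) gains are zero-filled so a full 10-vector is returned.
#' @export
posterior_mean <- function(samples, model = NULL) {
  mu <- colMeans(flat_draws(samples))
  if (is.null(model)) return(mu)
  full_theta(model, mu[.param_names[model$free]])
}

#' Pool chains with equal weight
#'
#' Concatenates all chains into a single-chain sample object (the naive
#' pooling baseline for multi-chain combination).
#'
#' @param samples an \code{erp_samples} object.
#' @export
pool_chains <- function(samples) {
  d <- dim(samples$draws)
  draws <- array(flat_draws(samples), c(1, d[1] * d[2], d[3]),
                 dimnames = list(NULL, NULL, samples$param_names))
  pw <- array(flat_pointwise(samples), c(1, d[1] * d[2], dim(samples$pointwise)[3]))
  stats <- lapply(samples$stats, function(s)
    if (is.matrix(s)) matrix(t(s), nrow = 1) else s)
  new_erp_samples(draws, pw, stats, paste0(samples$method, "+pooled"))
}

#' Persist posterior samples
#'
#' Writes a self-describing directory in an inference-data layout: one CSV
#' per group (\code{posterior.csv} with chain/iteration/parameter columns,
#' \code{sample_stats.csv}, \code{log_likelihood.csv}) plus a JSON manifest,
#' and a flat per-parameter summary CSV.
#'
#' @param samples an \code{erp_samples} object.
#' @param dir output directory (created if needed).
#' @export
write_samples <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(samples$draws)
  idx <- expand.grid(iteration = seq_len(d[2]), chain = seq_len(d[1]))
  post <- data.frame(chain = idx$chain, iteration = idx$iteration,
                     flat_draws(samples), check.names = FALSE)
  utils::write.csv(post, file.path(dir, "posterior.csv"), row.names = FALSE)
  st <- samples$stats[vapply(samples$stats, is.matrix, TRUE)]
  if (length(st)) {
    sm <- data.frame(chain = idx$chain, iteration = idx$iteration,
                     lapply(st, function(s) as.vector(t(s))))
    utils::write.csv(sm, file.path(dir, "sample_stats.csv"), row.names = FALSE)
  }
  ll <- data.frame(chain = idx$chain, iteration = idx$iteration,
                   flat_pointwise(samples))
  utils::write.csv(ll, file.path(dir, "log_likelihood.csv"), row.names = FALSE)
  utils::write.csv(summary(samples), file.path(dir, "summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(method = samples$method,
                            chains = d[1], iterations = d[2],
                            parameters = samples$param_names),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read posterior samples written by \code{write_samples}
#' @param dir directory produced by \code{write_samples}.
#' @export
read_samples <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  post <- utils::read.csv(file.path(dir, "posterior.csv"), check.names = FALSE)
  ll <- utils::read.csv(file.path(dir, "log_likelihood.csv"))
  C <- man$chains; S <- man$iterations
  pn <- man$parameters
  draws <- array(NA_real_, c(C, S, length(pn)), dimnames = list(NULL, NULL, pn))
  npt <- ncol(ll) - 2
  pw <- array(NA_real_, c(C, S, npt))
  for (c in seq_len(C)) {
    sel <- post$chain == c
    draws[c, , ] <- as.matrix(post[sel, pn, drop = FALSE])
    pw[c, , ] <- as.matrix(ll[ll$chain == c, -(1:2), drop = FALSE])
  }
  stats <- list()
  ssp <- file.path(dir, "sample_stats.csv")
  if (file.exists(ssp)) {
    ss <- utils::read.csv(ssp)
    for (nm in setdiff(names(ss), c("chain", "iteration")))
      stats[[nm]] <- matrix(ss[[nm]], nrow = C, byrow = TRUE)
  }
  new_erp_samples(draws, pw, stats, man$method)
}
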