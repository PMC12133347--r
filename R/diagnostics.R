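# Convergence and accuracy diagnostics: rank-normalized split R-hat, bulk and
# tail effective sample size, posterior z-scores, fit/parameter RMSE.

# chains x iterations matrix -> (2*chains) x floor(iterations/2) split halves
.split_chains <- function(m) {
  n <- ncol(m)
  half <- floor(n / 2)
  rbind(m[, seq_len(half), drop = FALSE],
        m[, (n - half + 1):n, drop = FALSE])
}

# fractional-rank inverse-normal transform over the pooled draws
.rank_normalize <- function(m) {
  r <- rank(as.vector(m), ties.method = "average")
  z <- qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  matrix(z, nrow(m), ncol(m))
}

# Gelman-Rubin potential scale reduction on a chains x iterations matrix.
.rhat_basic <- function(m) {
  n <- ncol(m)
  cm <- rowMeans(m)
  W <- mean(apply(m, 1, var))
  B <- n * var(cm)
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

#' Split rank-normalized R-hat
#'
#' Each chain is split in halves, pooled draws are rank-normalized through
#' the inverse normal transform of fractional ranks, and the Gelman-Rubin
#' between/within variance ratio is computed over the split chains. Values
#' near 1 indicate convergence; constant input yields NaN with a warning.
#'
#' @param draws chains x iterations matrix (a vector is treated as one
#'   chain).
#' @return Scalar R-hat.
#' @export
split_rhat <- function(draws) {
  m <- rbind(draws)
  if (ncol(m) < 2) stop("need at least 2 iterations per chain")
  if (diff(range(m)) == 0) {
    warning("constant draws: split R-hat undefined")
    return(NaN)
  }
  .rhat_basic(.rank_normalize(.split_chains(m)))
}

# Geyer initial-monotone-sequence ESS of a chains x iterations matrix
# (assumed already transformed as desired).
.ess_geyer <- function(m) {
  C <- nrow(m); n <- ncol(m)
  if (diff(range(m)) == 0) return(NaN)
  acov <- matrix(0, C, n)
  for (c in seq_len(C)) {
    a <- acf(m[c, ], lag.max = n - 1, plot = FALSE, type = "covariance",
             demean = TRUE)
    acov[c, ] <- a$acf[, 1, 1]
  }
  var_w <- mean(acov[, 1]) * n / (n - 1)
  var_plus <- var_w * (n - 1) / n + var(rowMeans(m))
  if (var_plus <= 0 || !is.finite(var_plus)) return(NaN)
  rho <- 1 - (var_w - colMeans(acov)) / var_plus   # rho[1] == lag 0
  # paired sums, initial monotone sequence
  max_pairs <- floor((n - 1) / 2)
  tau <- 1
  prev <- Inf
  for (p in seq_len(max_pairs)) {
    pair <- rho[2 * p] + rho[2 * p + 1]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev)
    prev <- pair
    tau <- tau + 2 * pair
  }
  ess <- C * n / tau
  min(ess, C * n * log10(max(C * n, 10)))
}

#' Bulk and tail effective sample size
#'
#' \code{ess_bulk} applies the Geyer initial-monotone-sequence estimator to
#' rank-normalized split chains. \code{ess_tail} is the minimum of the ESS of
#' the 5\% and 95\% quantile indicator series (split chains). Constant input
#' yields NaN with a warning.
#'
#' @param draws chains x iterations matrix (vector = one chain).
#' @return Scalar effective sample size.
#' @export
ess_bulk <- function(draws) {
  m <- rbind(draws)
  if (ncol(m) < 4) stop("need at least 4 iterations")
  if (diff(range(m)) == 0) {
    warning("constant draws: ESS undefined")
    return(NaN)
  }
  .ess_geyer(.rank_normalize(.split_chains(m)))
}

#' @rdname ess_bulk
#' @export
ess_tail <- function(draws) {
  m <- rbind(draws)
  if (ncol(m) < 4) stop("need at least 4 iterations")
  if (diff(range(m)) == 0) {
    warning("constant draws: ESS undefined")
    return(NaN)
  }
  ess_q <- function(p) {
    q <- quantile(as.vector(m), p, names = FALSE)
    ind <- .split_chains(matrix(as.numeric(m <= q), nrow(m), ncol(m)))
    if (diff(range(ind)) == 0) return(NaN)
    .ess_geyer(.rank_normalize(ind))
  }
  min(ess_q(0.05), ess_q(0.95))
}

#' Posterior z-scores against the generative truth
#'
#' Per-parameter \code{(posterior mean - truth) / posterior sd}, a combined
#' measure of bias and precision; near 0 in the ideal case.
#'
#' @param samples an \code{erp_samples} object.
#' @param truth named true parameter vector (defaults to the generative
#'   values); reduced parameters absent from the draws are skipped.
#' @export
z_scores <- function(samples, truth = nmm_params()) {
  m <- flat_draws(samples)
  mu <- colMeans(m)
  sdv <- apply(m, 2, sd)
  if (any(sdv == 0))
    stop("degenerate (zero-sd) posterior for parameter(s): ",
         paste(colnames(m)[sdv == 0], collapse = ", "))
  (mu - as.numeric(truth[colnames(m)])) / sdv
}

#' Fit and parameter recovery errors
#'
#' \code{rmse_fit}: root-mean-square error between the observed series and
#' the noise-free prediction at the posterior mean of the parameters; the
#' faithful-fit test is \code{rmse_fit <= threshold} (0.25 by default).
#' \code{rmse_params}: root-mean-square of per-parameter relative errors
#' \code{(mean - true)/true}, which puts parameters spanning two orders of
#' magnitude on a common scale.
#'
#' @param samples an \code{erp_samples} object.
#' @param model the \code{erp_model} the samples were drawn for.
#' @return \code{rmse_fit}: scalar (Inf when the posterior-mean simulation is
#'   unstable).
#' @export
rmse_fit <- function(samples, model) {
  mu <- posterior_mean(samples, model)
  pred <- predict_clean(model, mu)
  if (any(!is.finite(pred))) return(Inf)
  sqrt(mean((model$observation$y - pred)^2))
}

#' @rdname rmse_fit
#' @param truth named true parameter vector.
#' @export
rmse_params <- function(samples, truth = nmm_params()) {
  m <- flat_draws(samples)
  tr <- as.numeric(truth[colnames(m)])
  sqrt(mean(((colMeans(m) - tr) / tr)^2))
}

#' Full diagnostic panel for a fitted sample set
#'
#' @param samples an \code{erp_samples} object.
#' @param model the fitted \code{erp_model}.
#' @param truth generative parameter values for z-scores / parameter RMSE.
#' @param faithful_threshold fit-RMSE threshold for the faithful-fit label.
#' @return Object of class \code{fit_diagnostics}: list with per-parameter
#'   \code{r_hat}, \code{ess_bulk}, \code{ess_tail} (absolute and relative),
#'   \code{z_score}, plus \code{rmse_fit}, \code{rmse_params},
#'   \code{n_divergent} and logical \code{faithful}.
#' @export
fit_diagnostics <- function(samples, model, truth = nmm_params(),
                            faithful_threshold = 0.25) {
  pn <- samples$param_names
  total <- n_chains(samples) * n_draws(samples)
  per <- function(f) vapply(seq_along(pn), function(j)
    f(samples$draws[, , j, drop = TRUE]), numeric(1))
  rh <- per(split_rhat)
  eb <- per(ess_bulk)
  et <- per(ess_tail)
  out <- list(r_hat = setNames(rh, pn),
              ess_bulk = setNames(eb, pn),
              ess_tail = setNames(et, pn),
              rel_ess_bulk = setNames(eb / total, pn),
              rel_ess_tail = setNames(et / total, pn),
              z_score = setNames(z_scores(samples, truth), pn),
              rmse_fit = rmse_fit(samples, model),
              rmse_params = rmse_params(samples, truth),
              n_divergent = if (!is.null(samples$stats$divergent))
                sum(samples$stats$divergent) else NA_integer_)
  out$faithful <- is.finite(out$rmse_fit) && out$rmse_fit <= faithful_threshold
  class(out) <- "fit_diagnostics"
  out
}

#' @export
print.fit_diagnostics <- function(x, ...) {
  cat(sprintf("Fit diagnostics: RMSE fit %.4f (%s), RMSE params %.4f\n",
              x$rmse_fit, if (x$faithful) "faithful" else "failed",
              x$rmse_params))
  cat(sprintf("  mean R-hat %.3f | rel. bulk ESS %.2f | max |z| %.2f | divergences %s\n",
              mean(x$r_hat), mean(x$rel_ess_bulk), max(abs(x$z_score)),
              x$n_divergent))
  invisible(x)
}

#' Export a diagnostics table as CSV
#'
#' One row per entry of \code{diags} (e.g. per chain or per method), columns
#' matching the benchmark layout: mean R-hat, RMSE fit, min/max posterior
#' pairwise correlation, min/max |z|.
#'
#' @param diags named list of \code{fit_diagnostics}.
#' @param path output CSV path.
#' @export
write_diagnostics <- function(diags, path) {
  rows <- do.call(rbind, lapply(names(diags), function(nm) {
    d <- diags[[nm]]
    data.frame(label = nm, mean_rhat = mean(d$r_hat),
               rmse_fit = d$rmse_fit, rmse_params = d$rmse_params,
               rel_ess_bulk = mean(d$rel_ess_bulk),
               min_abs_z = min(abs(d$z_score)),
               max_abs_z = max(abs(d$z_score)),
               n_divergent = d$n_divergent, faithful = d$faithful)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(rows)
}
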