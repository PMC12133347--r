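# Front-end modelling interface: fit_erp() and methods on the fitted object.

#' Fit the ERP neural mass model to an observation series
#'
#' One-stop Bayesian inversion: builds (or accepts) the probabilistic model
#' and runs the chosen inference engine. Returns a classed fit supporting
#' \code{print}, \code{summary}, \code{coef}, \code{predict}, \code{plot},
#' \code{residuals} and \code{simulate}.
#'
#' @param observation an \code{erp_observation} (or an \code{erp_model}, in
#'   which case \code{priors}, \code{sigma_obs} and \code{reduced} are
#'   ignored).
#' @param engine \code{"nuts"} (default), \code{"meanfield"},
#'   \code{"fullrank"} or \code{"laplace"}.
#' @param priors,sigma_obs,reduced passed to \code{\link{erp_model}}.
#' @param config a \code{\link{sampler_config}} (NUTS) or
#'   \code{\link{vi_config}} (variational engines); defaults follow the
#'   study's benchmark settings with prior-tail initialization.
#' @param seed overrides the config seed when given.
#' @return Object of class \code{erp_fit}.
#' @export
#' @examples
#' \donttest{
#' obs <- generate_observation(seed = 1)
#' fit <- fit_erp(obs, config = sampler_config(n_chains = 2, n_warmup = 75,
#'                                             n_samples = 75, seed = 1))
#' summary(fit)
#' plot(fit)
#' }
fit_erp <- function(observation, engine = c("nuts", "meanfield", "fullrank",
                                            "laplace"),
                    priors = erp_priors(), sigma_obs = 0.1,
                    reduced = character(), config = NULL, seed = NULL) {
  engine <- match.arg(engine)
  model <- if (inherits(observation, "erp_model")) observation
           else erp_model(observation, priors, sigma_obs, reduced)
  if (is.null(config))
    config <- switch(engine,
      nuts = sampler_config(),
      meanfield = vi_config("mean_field"),
      fullrank = vi_config("full_rank"),
      laplace = vi_config("laplace"))
  if (!is.null(seed)) config$seed <- seed
  samples <- switch(engine,
    nuts = run_nuts(model, config),
    meanfield = run_advi(model, config),
    fullrank = run_advi(model, config),
    laplace = run_laplace(model, config))
  structure(list(model = model, samples = samples, engine = engine,
                 config = config),
            class = "erp_fit")
}

#' @export
print.erp_fit <- function(x, ...) {
  cat(sprintf("ERP model fit (engine: %s)\n", x$engine))
  print(x$model)
  print(x$samples)
  cat(sprintf("posterior-mean fit RMSE: %.4f\n",
              rmse_fit(x$samples, x$model)))
  invisible(x)
}

#' @export
summary.erp_fit <- function(object, truth = nmm_params(), ...) {
  tab <- summary(object$samples)
  tab$r_hat <- vapply(seq_len(nrow(tab)), function(j)
    split_rhat(object$samples$draws[, , j, drop = TRUE]), 0)
  tab$ess_bulk <- vapply(seq_len(nrow(tab)), function(j)
    ess_bulk(object$samples$draws[, , j, drop = TRUE]), 0)
  out <- list(engine = object$engine, parameters = tab,
              rmse_fit = rmse_fit(object$samples, object$model),
              diagnostics = fit_diagnostics(object$samples, object$model,
                                            truth = truth))
  class(out) <- "summary.erp_fit"
  out
}

#' @export
print.summary.erp_fit <- function(x, ...) {
  cat(sprintf("Engine: %s\n", x$engine))
  print(x$parameters, digits = 4)
  print(x$diagnostics)
  invisible(x)
}

#' @export
coef.erp_fit <- function(object, ...) {
  posterior_mean(object$samples, object$model)
}

#' Posterior-mean model prediction
#'
#' @param object an \code{erp_fit}.
#' @param type \code{"mean"} for the noise-free prediction at the posterior
#'   mean of the parameters, \code{"draws"} for per-draw predictions (rows =
#'   draws, subsampled to at most \code{n_max}).
#' @param n_max maximum number of per-draw predictions.
#' @param ... unused.
#' @export
predict.erp_fit <- function(object, type = c("mean", "draws"), n_max = 100,
                            ...) {
  type <- match.arg(type)
  if (type == "mean")
    return(predict_clean(object$model, coef(object)))
  fl <- flat_draws(object$samples)
  idx <- unique(round(seq(1, nrow(fl), length.out = min(n_max, nrow(fl)))))
  t(vapply(idx, function(i)
    predict_clean(object$model,
                  full_theta(object$model, fl[i, ])),
    numeric(length(object$model$observation$y))))
}

#' @export
residuals.erp_fit <- function(object, ...) {
  object$model$observation$y - predict(object, "mean")
}

#' Posterior predictive simulation
#'
#' Draws parameter vectors from the posterior, forward-simulates each and
#' adds observation noise at the model's likelihood sd.
#'
#' @param object an \code{erp_fit}.
#' @param nsim number of replicated observation series.
#' @param seed integer seed.
#' @param ... unused.
#' @return Matrix \code{nsim} x N of replicated observations.
#' @export
simulate.erp_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  fl <- flat_draws(object$samples)
  idx <- sample.int(nrow(fl), nsim, replace = TRUE)
  N <- length(object$model$observation$y)
  out <- matrix(NA_real_, nsim, N)
  for (i in seq_len(nsim)) {
    pred <- predict_clean(object$model, full_theta(object$model, fl[idx[i], ]))
    out[i, ] <- pred + rnorm(N, 0, object$model$sigma_obs)
  }
  out
}

#' @export
plot.erp_fit <- function(x, ...) {
  obs <- x$model$observation
  graphics::plot(obs$times, obs$y, pch = 16, cex = 0.4, col = "grey50",
                 xlab = "time (ms)", ylab = "pyramidal voltage", ...)
  pd <- predict(x, "draws", n_max = 30)
  for (i in seq_len(nrow(pd)))
    graphics::lines(obs$times, pd[i, ], col = grDevices::adjustcolor("orange", 0.25))
  graphics::lines(obs$times, predict(x, "mean"), col = "red", lwd = 2)
  invisible(x)
}

#' @export
logLik.erp_fit <- function(object, ...) {
  ll <- sum(pointwise_loglik(object$model, coef(object)))
  attr(ll, "df") <- sum(object$model$free)
  class(ll) <- "logLik"
  ll
}
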