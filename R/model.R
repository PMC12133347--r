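# Bayesian model: Gamma priors + Gaussian likelihood over the observation
# series, log/exp reparametrization to unconstrained space, and the gradient
# of the log joint used by every gradient-based engine.

#' Bayesian ERP model
#'
#' Binds an observation series to the Gamma prior set and the Gaussian
#' likelihood with fixed noise sd \code{sigma_obs} (the generative value 0.1
#' by default; the noise sd is not inferred). A reduced model structurally
#' fixes a subset of the connectivity gains \code{g1..g4} at zero and removes
#' them from the sampled vector, so the unconstrained dimension is
#' \code{10 - length(reduced)}.
#'
#' @param observation an \code{erp_observation} (or a list with \code{times}
#'   in ms and \code{y}).
#' @param priors a \code{gamma_priors} object.
#' @param sigma_obs likelihood sd (default 0.1).
#' @param reduced character vector naming gains fixed at 0 (subset of
#'   \code{c("g1","g2","g3","g4")}).
#' @param dt integration step in ms used for the forward model (default 0.1).
#' @param blowup instability bound (default 1e3); draws whose forward
#'   simulation blows up receive log-density \code{-Inf}.
#' @return Object of class \code{erp_model}.
#' @export
#' @examples
#' obs <- generate_observation(seed = 1)
#' m <- erp_model(obs)
#' log_joint(m, nmm_params())
erp_model <- function(observation, priors = erp_priors(), sigma_obs = 0.1,
                      reduced = character(), dt = 0.1, blowup = 1e3) {
  stopifnot(length(observation$times) == length(observation$y),
            length(observation$y) >= 2, sigma_obs > 0)
  if (length(reduced) && !all(reduced %in% c("g1", "g2", "g3", "g4")))
    stop("only connectivity gains g1..g4 can be reduced to zero")
  reduced <- unique(reduced)
  spacing <- diff(observation$times)
  if (any(abs(spacing - spacing[1]) > 1e-8))
    stop("observation times must be uniformly spaced")
  ds <- round(spacing[1] / dt)
  if (abs(ds * dt - spacing[1]) > 1e-8)
    stop("observation spacing must be a multiple of dt")
  free <- !(.param_names %in% reduced)
  structure(list(observation = observation, priors = priors,
                 sigma_obs = sigma_obs, reduced = reduced, free = free,
                 dt = dt, downsample = as.integer(ds),
                 n_steps = as.integer(ds * (length(observation$y) - 1)),
                 blowup = blowup),
            class = "erp_model")
}

#' @export
print.erp_model <- function(x, ...) {
  cat(sprintf("Bayesian ERP model: %d observations, sigma = %g, %d free parameters%s\n",
              length(x$observation$y), x$sigma_obs, sum(x$free),
              if (length(x$reduced)) paste0(" (", paste(x$reduced, collapse = ","),
                                            " = 0)") else ""))
  invisible(x)
}

# Assemble a full 10-vector from the free coordinates of a (possibly reduced)
# model, zero-filling the masked gains.
full_theta <- function(model, theta_free) {
  th <- numeric(length(.param_names))
  names(th) <- .param_names
  th[model$free] <- theta_free
  th
}

#' Pointwise log-likelihood
#'
#' Gaussian log-density of each observed point given the model-predicted
#' downsampled pyramidal voltage at the parameter value, with the fixed
#' likelihood sd. Returns a vector of \code{-Inf} when the forward
#' simulation is unstable.
#'
#' @param model an \code{erp_model}.
#' @param params full parameter vector (canonical order or named).
#' @return Numeric vector, one element per observation point.
#' @export
pointwise_loglik <- function(model, params) {
  r <- .nmm_loglik_grad_cpp(as.numeric(params), model$observation$y, model$dt,
                            model$n_steps, model$downsample, model$sigma_obs,
                            1.0, model$blowup, FALSE)
  as.numeric(r$pointwise)
}

#' Noise-free model prediction
#'
#' @param model an \code{erp_model}.
#' @param params full parameter vector.
#' @return Predicted pyramidal voltage at the observation times
#'   (NA-padded if the simulation is unstable).
#' @export
predict_clean <- function(model, params) {
  r <- .nmm_predict_cpp(as.numeric(params), model$dt, model$n_steps,
                        model$downsample, 1.0, model$blowup)
  as.numeric(r$pred)
}

#' Log joint density
#'
#' \code{log_prior + sum(pointwise_loglik)}; \code{-Inf} outside the prior
#' support or on dynamically unstable draws.
#'
#' @inheritParams pointwise_loglik
#' @export
log_joint <- function(model, params) {
  lp <- log_prior(params, model$priors, model$reduced)
  if (!is.finite(lp)) return(-Inf)
  lp + sum(pointwise_loglik(model, params))
}

#' Map between constrained and unconstrained parameter space
#'
#' The sampled (free) parameters are positive; engines operate on the
#' componentwise log. \code{to_unconstrained} maps free parameters to
#' \eqn{\zeta = \log\theta}; \code{from_unconstrained} inverts it. The
#' log-Jacobian of the inverse map is \eqn{\sum_k \zeta_k}.
#'
#' @param model an \code{erp_model}.
#' @param params full parameter vector (only free coordinates are used).
#' @return \code{to_unconstrained}: unconstrained vector of length
#'   \code{sum(model$free)}.
#' @export
to_unconstrained <- function(model, params) {
  th <- as.numeric(params)[model$free]
  if (any(th <= 0)) stop("free parameters must be strictly positive")
  setNames(log(th), .param_names[model$free])
}

#' @rdname to_unconstrained
#' @param zeta unconstrained vector.
#' @return \code{from_unconstrained}: full named 10-vector with masked gains
#'   at 0.
#' @export
from_unconstrained <- function(model, zeta) {
  full_theta(model, exp(as.numeric(zeta)))
}

# Unconstrained-space log density (log joint + log |Jacobian|) and its
# gradient. This is the single target every engine works on. Returns the
# pointwise log-likelihood alongside so samplers can record it for free.
log_post_unconstrained <- function(model, zeta, grad = TRUE) {
  th_free <- exp(as.numeric(zeta))
  theta <- full_theta(model, th_free)
  free <- model$free
  pr <- model$priors
  lp <- sum(dgamma(th_free, shape = pr$shape[free], scale = pr$scale[free],
                   log = TRUE))
  if (!is.finite(lp))
    return(list(value = -Inf, grad = rep(0, sum(free)),
                loglik = -Inf, pointwise = rep(-Inf, model$n_steps %/%
                                                 model$downsample + 1)))
  r <- .nmm_loglik_grad_cpp(as.numeric(theta), model$observation$y, model$dt,
                            model$n_steps, model$downsample, model$sigma_obs,
                            1.0, model$blowup, grad)
  value <- lp + r$loglik + sum(zeta)
  if (!grad || !is.finite(value))
    return(list(value = if (is.finite(value)) value else -Inf,
                grad = rep(0, sum(free)), loglik = r$loglik,
                pointwise = as.numeric(r$pointwise)))
  g_con <- log_prior_grad(th_free, pr, free) + as.numeric(r$grad)[free]
  list(value = value, grad = g_con * th_free + 1, loglik = r$loglik,
       pointwise = as.numeric(r$pointwise))
}

#' Reduced connectivity model
#'
#' Returns a copy of the model with one connectivity gain structurally fixed
#' at zero and excluded from sampling (the free dimension drops by one).
#' Reducing an already-reduced gain is idempotent.
#'
#' @param model an \code{erp_model}.
#' @param zero_param one of \code{"g1"}, \code{"g2"}, \code{"g3"},
#'   \code{"g4"}.
#' @export
reduced_model <- function(model, zero_param) {
  stopifnot(inherits(model, "erp_model"))
  if (!zero_param %in% c("g1", "g2", "g3", "g4"))
    stop("only connectivity gains g1..g4 can be reduced")
  erp_model(model$observation, model$priors, model$sigma_obs,
            reduced = union(model$reduced, zero_param),
            dt = model$dt, blowup = model$blowup)
}
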