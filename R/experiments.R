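# Orchestration of the simulation experiments: hyperparameter grid search,
# tail-initialization, chain stacking, the four-engine benchmark, the
# five-model comparison, and the prior-predictive stability screen.

#' Default NUTS hyperparameter grid
#'
#' 20 settings: target acceptance in \{0.6, 0.7, 0.8, 0.9, 0.95\} crossed
#' with maximum tree depth in \{5, 6, 7, 8\}.
#'
#' @export
default_grid <- function() {
  expand.grid(target_accept = c(0.6, 0.7, 0.8, 0.9, 0.95),
              max_tree_depth = c(5, 6, 7, 8))
}

# Single-chain view of a multi-chain sample object.
.chain_subset <- function(samples, c) {
  new_erp_samples(samples$draws[c, , , drop = FALSE],
                  samples$pointwise[c, , , drop = FALSE],
                  lapply(samples$stats, function(s)
                    if (is.matrix(s)) s[c, , drop = FALSE] else s),
                  samples$method)
}

.write_manifest <- function(out_dir, config, seed) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("erpdcm")),
         seed = seed, config = config),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
}

# Shared engine for the grid and tails experiments: one NUTS run per grid
# setting, one diagnostics row per chain.
.run_grid_core <- function(observation, grid, init_strategy, n_chains,
                           n_warmup, n_samples, seed, truth,
                           faithful_threshold = 0.25) {
  model <- erp_model(observation)
  rows <- list()
  for (g in seq_len(nrow(grid))) {
    cfg <- sampler_config(n_chains = n_chains, n_warmup = n_warmup,
                          n_samples = n_samples,
                          max_tree_depth = grid$max_tree_depth[g],
                          target_accept = grid$target_accept[g],
                          init_strategy = init_strategy,
                          seed = seed + 10000 * g)
    samples <- tryCatch(run_nuts(model, cfg), error = identity)
    for (c in seq_len(n_chains)) {
      if (inherits(samples, "error") || c > n_chains(samples)) {
        rows[[length(rows) + 1]] <- data.frame(
          setting = g, target_accept = grid$target_accept[g],
          max_tree_depth = grid$max_tree_depth[g], chain = c,
          rmse_fit = Inf, rmse_params = NA_real_, log_prob = NA_real_,
          split_rhat = NA_real_, rel_ess_bulk = NA_real_,
          step_size = NA_real_, n_divergent = NA_integer_,
          faithful = FALSE, failed = TRUE)
        next
      }
      ch <- .chain_subset(samples, c)
      rf <- rmse_fit(ch, model)
      rh <- vapply(seq_len(dim(ch$draws)[3]), function(j)
        suppressWarnings(split_rhat(ch$draws[, , j, drop = TRUE])), 0)
      eb <- vapply(seq_len(dim(ch$draws)[3]), function(j)
        suppressWarnings(ess_bulk(ch$draws[, , j, drop = TRUE])), 0)
      rows[[length(rows) + 1]] <- data.frame(
        setting = g, target_accept = grid$target_accept[g],
        max_tree_depth = grid$max_tree_depth[g], chain = c,
        rmse_fit = rf, rmse_params = rmse_params(ch, truth),
        log_prob = mean(ch$stats$lp), split_rhat = mean(rh),
        rel_ess_bulk = mean(eb) / n_draws(ch),
        step_size = ch$stats$step_size[1, 1],
        n_divergent = sum(ch$stats$divergent),
        faithful = is.finite(rf) && rf <= faithful_threshold,
        failed = !is.finite(rf) || rf > faithful_threshold)
    }
  }
  do.call(rbind, rows)
}

#' NUTS hyperparameter grid-search experiment
#'
#' Runs \code{n_chains} randomly (prior-) initialized chains for every grid
#' setting and records per-chain fit RMSE, parameter RMSE, log probability,
#' split R-hat, relative bulk ESS, step size and the faithful/failed label
#' (threshold 0.25). Individual chain failures are recorded, never fatal.
#'
#' @param observation an \code{erp_observation} (defaults to the study
#'   series with \code{seed}).
#' @param grid data frame with columns \code{target_accept},
#'   \code{max_tree_depth} (default \code{\link{default_grid}}).
#' @param n_chains,n_warmup,n_samples per-setting chain budget.
#' @param seed integer seed.
#' @param truth generative parameters for recovery error.
#' @param out_dir optional output directory (CSV + manifest).
#' @return Data frame, one row per chain.
#' @export
run_grid_experiment <- function(observation = generate_observation(seed = seed),
                                grid = default_grid(), n_chains = 4,
                                n_warmup = 200, n_samples = 200, seed = 1,
                                truth = nmm_params(), out_dir = NULL) {
  tab <- .run_grid_core(observation, grid, "random", n_chains, n_warmup,
                        n_samples, seed, truth)
  .write_manifest(out_dir, list(experiment = "grid", grid = grid,
                                n_chains = n_chains, n_warmup = n_warmup,
                                n_samples = n_samples), seed)
  if (!is.null(out_dir))
    utils::write.csv(tab, file.path(out_dir, "grid.csv"), row.names = FALSE)
  tab
}

#' Tail-initialization experiment
#'
#' Identical to \code{\link{run_grid_experiment}} but every chain is
#' initialized at an independent draw from the tails of the prior, the
#' remedy that removes convergence failures.
#'
#' @inheritParams run_grid_experiment
#' @export
run_tails_experiment <- function(observation = generate_observation(seed = seed),
                                 grid = default_grid(), n_chains = 4,
                                 n_warmup = 200, n_samples = 200, seed = 1,
                                 truth = nmm_params(), out_dir = NULL) {
  tab <- .run_grid_core(observation, grid, "prior_tails", n_chains, n_warmup,
                        n_samples, seed, truth)
  .write_manifest(out_dir, list(experiment = "tails", grid = grid,
                                n_chains = n_chains, n_warmup = n_warmup,
                                n_samples = n_samples), seed)
  if (!is.null(out_dir))
    utils::write.csv(tab, file.path(out_dir, "tails.csv"), row.names = FALSE)
  tab
}

#' Chain-stacking experiment
#'
#' Runs randomly initialized NUTS chains (some of which typically converge
#' to spurious modes), computes chain stacking weights from PSIS-LOO
#' predictive densities, and compares the stacked mixture against naive
#' equal-weight pooling: predictive traces (mixture means) and their RMSE
#' against the observation.
#'
#' @inheritParams run_grid_experiment
#' @param n_chains number of randomly initialized chains.
#' @param config optional \code{sampler_config} overriding the defaults.
#' @return List with \code{weights} (stacking result), \code{rmse_stacked},
#'   \code{rmse_pooled}, \code{pred_stacked}, \code{pred_pooled}, per-chain
#'   \code{chain_table}, and the \code{samples}.
#' @export
run_stacking_experiment <- function(observation = generate_observation(seed = seed),
                                    n_chains = 8, n_warmup = 200,
                                    n_samples = 200, seed = 1,
                                    config = NULL, out_dir = NULL) {
  model <- erp_model(observation)
  if (is.null(config))
    config <- sampler_config(n_chains = n_chains, n_warmup = n_warmup,
                             n_samples = n_samples,
                             init_strategy = "random", seed = seed)
  samples <- run_nuts(model, config)
  sw <- stack_weights_chains(samples)
  C <- n_chains(samples)
  # per-chain posterior-mean predictions
  preds <- t(vapply(seq_len(C), function(c)
    predict_clean(model, posterior_mean(.chain_subset(samples, c), model)),
    numeric(length(observation$y))))
  ok <- is.finite(rowSums(preds))
  w <- sw$weights
  pred_stacked <- colSums(preds[ok, , drop = FALSE] * (w[ok] / sum(w[ok])))
  pred_pooled <- colMeans(preds[ok, , drop = FALSE])
  chain_tab <- data.frame(chain = seq_len(C), weight = w,
                          rmse_fit = vapply(seq_len(C), function(c)
                            rmse_fit(.chain_subset(samples, c), model), 0))
  chain_tab$faithful <- is.finite(chain_tab$rmse_fit) & chain_tab$rmse_fit <= 0.25
  out <- list(weights = sw,
              rmse_stacked = sqrt(mean((observation$y - pred_stacked)^2)),
              rmse_pooled = sqrt(mean((observation$y - pred_pooled)^2)),
              pred_stacked = pred_stacked, pred_pooled = pred_pooled,
              chain_table = chain_tab, samples = samples)
  .write_manifest(out_dir, list(experiment = "stack", n_chains = C,
                                n_warmup = n_warmup, n_samples = n_samples),
                  seed)
  if (!is.null(out_dir)) {
    utils::write.csv(chain_tab, file.path(out_dir, "chains.csv"),
                     row.names = FALSE)
    write_stacking(sw, file.path(out_dir, "weights.json"))
  }
  out
}

#' Four-engine benchmark experiment
#'
#' Fits the model with NUTS and the three variational engines (mean-field,
#' full-rank, Laplace), all tail-initialized, and reports per method: mean
#' split R-hat, fit RMSE, min/max posterior pairwise correlation and min/max
#' |z-score|. Variational engines are run as independent repetitions (one
#' per "chain") to mirror the multi-chain layout.
#'
#' @inheritParams run_grid_experiment
#' @param nuts_config,vi_iters engine budgets.
#' @return List with the report data frame (\code{table}) and the per-method
#'   sample objects.
#' @export
run_benchmark_experiment <- function(observation = generate_observation(seed = seed),
                                     nuts_config = NULL, vi_iters = 1e5,
                                     seed = 1, truth = nmm_params(),
                                     out_dir = NULL) {
  model <- erp_model(observation)
  if (is.null(nuts_config))
    nuts_config <- sampler_config(init_strategy = "prior_tails", seed = seed)
  fits <- list()
  fits$nuts <- run_nuts(model, nuts_config)
  n_rep <- nuts_config$n_chains
  for (guide in c("mean_field", "full_rank", "laplace")) {
    reps <- lapply(seq_len(n_rep), function(r) {
      cfg <- vi_config(guide, n_iters = vi_iters, n_chains = 1,
                       n_samples = nuts_config$n_samples,
                       init_strategy = "prior_tails",
                       seed = seed + 100 * r)
      if (guide == "laplace") run_laplace(model, cfg) else run_advi(model, cfg)
    })
    draws <- do.call(abind3, lapply(reps, function(s) s$draws))
    pw <- do.call(abind3, lapply(reps, function(s) s$pointwise))
    lbl <- c(mean_field = "meanfield", full_rank = "fullrank",
             laplace = "laplace")[[guide]]
    fits[[lbl]] <- new_erp_samples(
      draws, pw,
      list(lp = do.call(rbind, lapply(reps, function(s) s$stats$lp)),
           loglik = do.call(rbind, lapply(reps, function(s) s$stats$loglik))),
      lbl,
      extra = list(free_energy = mean(vapply(reps, function(s)
        s$free_energy, 0))))
  }
  tab <- do.call(rbind, lapply(names(fits), function(nm) {
    s <- fits[[nm]]
    d <- fit_diagnostics(s, model, truth)
    corr <- stats::cor(flat_draws(s))
    off <- abs(corr[upper.tri(corr)])
    data.frame(method = nm, mean_rhat = mean(d$r_hat),
               rmse_fit = d$rmse_fit,
               min_corr = min(off), max_corr = max(off),
               min_abs_z = min(abs(d$z_score)),
               max_abs_z = max(abs(d$z_score)),
               rel_ess_bulk = mean(d$rel_ess_bulk))
  }))
  .write_manifest(out_dir, list(experiment = "benchmark",
                                vi_iters = vi_iters), seed)
  if (!is.null(out_dir))
    utils::write.csv(tab, file.path(out_dir, "benchmark.csv"),
                     row.names = FALSE)
  list(table = tab, fits = fits)
}

# bind 3-d arrays along the first (chain) dimension
abind3 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  out <- array(NA_real_, c(sum(vapply(arrs, function(a) dim(a)[1], 0L)),
                           d[2], d[3]),
               dimnames = list(NULL, NULL, dimnames(arrs[[1]])[[3]]))
  at <- 0
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Five-model comparison experiment
#'
#' Fits the full model and the four single-gain reductions (g1 = 0 ... g4 =
#' 0) and scores each with AIC, BIC, WAIC, PSIS-LOO (and the variational
#' free energy when variational engines are requested).
#'
#' @inheritParams run_grid_experiment
#' @param engines subset of \code{c("nuts", "meanfield", "fullrank",
#'   "laplace")}; criteria come from the first engine's samples, free energy
#'   from the variational ones.
#' @param nuts_config,vi_iters engine budgets.
#' @return List with the ranking \code{table} (see
#'   \code{\link{compare_models}}), per-model \code{scores}, fit RMSE per
#'   model, and free-energy table per variational engine.
#' @export
run_model_comparison_experiment <- function(observation = generate_observation(seed = seed),
                                            engines = "nuts",
                                            nuts_config = NULL, vi_iters = 2e4,
                                            seed = 1, out_dir = NULL) {
  if (is.null(nuts_config))
    nuts_config <- sampler_config(init_strategy = "prior_tails", seed = seed)
  models <- list(full = character(), g1 = "g1", g2 = "g2", g3 = "g3",
                 g4 = "g4")
  scores <- list(); rmse <- numeric(); fe <- list()
  for (nm in names(models)) {
    model <- erp_model(observation, reduced = models[[nm]])
    s <- run_nuts(model, nuts_config)
    scores[[nm]] <- comparison_scores(s, model)
    rmse[nm] <- rmse_fit(s, model)
    for (guide in intersect(engines, c("meanfield", "fullrank", "laplace"))) {
      g <- c(meanfield = "mean_field", fullrank = "full_rank",
             laplace = "laplace")[[guide]]
      cfg <- vi_config(g, n_iters = vi_iters, n_chains = 1,
                       n_samples = nuts_config$n_samples,
                       init_strategy = "prior_tails", seed = seed)
      vs <- tryCatch(if (guide == "laplace") run_laplace(model, cfg)
                     else run_advi(model, cfg), error = identity)
      fe[[guide]][nm] <- if (inherits(vs, "error")) NA_real_
                         else vs$free_energy
    }
  }
  tab <- compare_models(scores)
  tab$rmse_fit <- rmse[tab$model]
  for (guide in names(fe)) tab[[paste0("free_energy_", guide)]] <-
    -fe[[guide]][tab$model]   # deviance-like scale: smaller = better
  .write_manifest(out_dir, list(experiment = "compare", engines = engines),
                  seed)
  if (!is.null(out_dir)) {
    utils::write.csv(tab, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
    jsonlite::write_json(lapply(scores, function(s)
      s[c("aic", "bic", "waic", "elpd_psis_loo", "k", "n")]),
      file.path(out_dir, "scores.json"), auto_unbox = TRUE, digits = NA)
  }
  list(table = tab, scores = scores, rmse_fit = rmse, free_energy = fe)
}

#' Prior-predictive stability screen
#'
#' Draws \code{n} parameter sets from the priors, classifies the dynamics of
#' each (see \code{\link{classify_dynamics}}), and reports the unstable
#' percentage with a 95\% binomial confidence interval.
#'
#' @param priors a \code{gamma_priors} object.
#' @param n number of prior draws.
#' @param seed integer seed.
#' @param out_dir optional output directory.
#' @return List with \code{percent_unstable}, \code{ci} (95\% normal
#'   approximation), \code{n}, and the logical vector \code{unstable}.
#' @export
run_prior_predictive <- function(priors = erp_priors(), n = 1000, seed = 1,
                                 out_dir = NULL) {
  set.seed(seed)
  draws <- sample_prior(priors, n)
  unstable <- apply(draws, 1, function(p)
    classify_dynamics(p) == "unstable")
  p_hat <- mean(unstable)
  half <- 1.96 * sqrt(p_hat * (1 - p_hat) / n)
  out <- list(percent_unstable = 100 * p_hat,
              ci = 100 * c(max(0, p_hat - half), min(1, p_hat + half)),
              n = n, unstable = unstable)
  .write_manifest(out_dir, list(experiment = "prior-predictive", n = n), seed)
  if (!is.null(out_dir))
    jsonlite::write_json(out[c("percent_unstable", "ci", "n")],
                         file.path(out_dir, "prior_predictive.json"),
                         auto_unbox = TRUE, digits = NA)
  out
}
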