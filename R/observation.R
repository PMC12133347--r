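# Synthetic observation series: noisy, downsampled pyramidal voltage.

#' Generate the synthetic ERP observation series
#'
#' Integrates the model for \code{duration} ms at step \code{dt} ms with the
#' step input active, adds i.i.d. zero-mean Gaussian noise with standard
#' deviation \code{sigma_obs} to every pyramidal-voltage sample (noise is
#' added on the full-resolution grid, before downsampling), then retains
#' every \code{downsample}-th sample starting at index 0. Defaults reproduce
#' the study conditions: 2001 noisy samples downsampled by 10 to 201 points.
#'
#' @param params an \code{nmm_params} vector (default: the generative truth).
#' @param seed integer seed; the generator is reproducible given the seed.
#' @param sigma_obs observation-noise sd (default 0.1; may be 0).
#' @param downsample integer downsampling factor (default 10).
#' @param dt,duration integration step and window in ms.
#' @return Object of class \code{erp_observation}: list with \code{times}
#'   (ms, retained grid), \code{y} (observed voltages), \code{clean} (the
#'   noise-free retained x9 samples), \code{sigma_obs}, \code{downsample},
#'   \code{dt}, \code{seed}.
#' @export
#' @examples
#' obs <- generate_observation(seed = 1)
#' length(obs$y)  # 201
generate_observation <- function(params = nmm_params(), seed = 1,
                                 sigma_obs = 0.1, downsample = 10,
                                 dt = 0.1, duration = 200) {
  stopifnot(sigma_obs >= 0, downsample >= 1)
  traj <- simulate_nmm(params, dt = dt, duration = duration)
  if (!traj$stable)
    stop("parameter set ", paste(signif(as.numeric(params), 4), collapse = ", "),
         " yields an unstable forward simulation; cannot generate observations")
  x9 <- traj$states[, "x9"]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  noisy <- x9 + rnorm(length(x9), mean = 0, sd = sigma_obs)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  keep <- seq(1, length(x9), by = downsample)
  structure(list(times = traj$times[keep], y = noisy[keep],
                 clean = x9[keep], sigma_obs = sigma_obs,
                 downsample = downsample, dt = dt, seed = as.integer(seed)),
            class = "erp_observation")
}

#' @export
print.erp_observation <- function(x, ...) {
  cat(sprintf("ERP observation series: %d points over %g ms (sigma = %g, seed = %d)\n",
              length(x$y), max(x$times), x$sigma_obs, x$seed))
  invisible(x)
}

#' @export
plot.erp_observation <- function(x, ...) {
  graphics::plot(x$times, x$y, type = "p", pch = 16, cex = 0.4, col = "grey40",
                 xlab = "time (ms)", ylab = "pyramidal voltage", ...)
  graphics::lines(x$times, x$clean, col = "red")
  invisible(x)
}

#' Save / load an observation series as CSV
#'
#' The file holds a comment line \code{# seed=<n> sigma=<s>} followed by the
#' header \code{time_ms,y}. Round trips reproduce values to full precision.
#'
#' @param obs an \code{erp_observation} (or any list with \code{times},
#'   \code{y}).
#' @param path file path.
#' @export
save_observation <- function(obs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%s sigma=%s",
                     if (is.null(obs$seed)) "NA" else obs$seed,
                     if (is.null(obs$sigma_obs)) "NA" else
                       format(obs$sigma_obs, digits = 17)), con)
  writeLines("time_ms,y", con)
  writeLines(paste(format(obs$times, digits = 17, trim = TRUE),
                   format(obs$y, digits = 17, trim = TRUE), sep = ","), con)
  invisible(path)
}

#' @rdname save_observation
#' @return \code{load_observation}: an \code{erp_observation} (with
#'   \code{clean} unset when not derivable from the file).
#' @export
load_observation <- function(path) {
  lines <- readLines(path)
  meta <- grepl("^#", lines)
  seed <- NA_integer_; sigma <- NA_real_
  if (any(meta)) {
    m <- regmatches(lines[meta][1],
                    regexec("seed=([^ ]+) sigma=([^ ]+)", lines[meta][1]))[[1]]
    if (length(m) == 3) {
      seed <- suppressWarnings(as.integer(m[2]))
      sigma <- suppressWarnings(as.numeric(m[3]))
    }
  }
  body <- lines[!meta]
  if (length(body) < 2)
    stop("malformed observation table at line ", sum(meta) + length(body),
         ": need a header and at least one data row")
  dat <- utils::read.csv(text = body, header = TRUE)
  if (ncol(dat) < 2)
    stop("malformed observation table at line ", sum(meta) + 1,
         ": expected two columns (time, value)")
  if (nrow(dat) == 0 || any(!complete.cases(dat[, 1:2])))
    stop("malformed observation table: non-numeric or missing entries")
  times <- as.numeric(dat[[1]]); y <- as.numeric(dat[[2]])
  dt_grid <- unique(round(diff(times), 10))
  structure(list(times = times, y = y, clean = NULL,
                 sigma_obs = sigma, downsample = NA_integer_,
                 dt = if (length(dt_grid) == 1) dt_grid else NA_real_,
                 seed = seed),
            class = "erp_observation")
}
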