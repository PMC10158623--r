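# Weighted least-squares calibration of the kinetic model against
# multi-experiment shake-flask time series, and Monte-Carlo quantification of
# parameter uncertainty by data perturbation and refitting.

#' Time-series dataset for calibration
#'
#' A grouped collection of experiments, each carrying its culture setup, an
#' observation table (`time_h` plus any subset of the observable state
#' columns) and a relative measurement error.
#'
#' @param experiments a list; each element needs `setup` (a
#'   [culture_setup()]), `observations` (data frame whose first column is
#'   `time_h`, strictly increasing) and `rel_error` (> 0).
#' @return an object of class `ts_dataset`.
#' @export
ts_dataset <- function(experiments) {
  stopifnot(is.list(experiments), length(experiments) >= 1)
  for (i in seq_along(experiments)) {
    e <- experiments[[i]]
    if (!inherits(e$setup, "culture_setup"))
      stop("experiment ", i, ": setup must be a culture_setup")
    obs <- e$observations
    if (!is.data.frame(obs) || !"time_h" %in% names(obs))
      stop("experiment ", i, ": observations need a time_h column")
    if (any(diff(obs$time_h) <= 0))
      stop("experiment ", i, ": times must be strictly increasing")
    if (is.null(e$rel_error) || e$rel_error <= 0)
      stop("experiment ", i, ": rel_error must be > 0")
    vars <- intersect(names(obs), .observables)
    if (length(vars) == 0)
      stop("experiment ", i, ": no observable columns found")
  }
  structure(experiments, class = "ts_dataset")
}

# parameters estimated by default; the rest are held at their initial values.
# Half-saturations of glucose/glutamine uptake, the attachment and lysis
# constants and the death-curve shape are weakly identifiable from a
# standard batch grid and stay fixed unless the caller frees them.
.default_free <- c("mu_max", "K_S_LS", "mu_d_min", "q_LS_max",
                   "Y_X_Glc", "Y_X_Gln", "Y_Lac_Glc", "Y_Amm_Gln")

# weighted residual vector for one candidate parameter set over all
# experiments: (obs - pred) / (rel_error * per-observable scale)
.wresiduals <- function(data, params, death_mode, rtol = 1e-6, atol = 1e-8) {
  res <- numeric(0)
  for (e in data) {
    tg <- e$observations$time_h
    sim <- tryCatch(
      simulate_batch(e$setup, params, t_grid = tg, rtol = rtol, atol = atol,
                     death_mode = death_mode),
      error = function(err) NULL)
    vars <- intersect(names(e$observations), .observables)
    if (is.null(sim)) return(NULL)
    for (v in vars) {
      o <- e$observations[[v]]
      keep <- is.finite(o)
      if (!any(keep)) next
      sc <- mean(abs(o[keep]))
      if (sc <= 0) sc <- 1
      res <- c(res, (o[keep] - sim[[v]][keep]) / (e$rel_error * sc))
    }
  }
  res
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res/SS_tot` with the total sum of squares about the observed
#' mean. Zero-variance observations are handled by convention: 1 when the
#' residuals are all (numerically) zero, otherwise 0.
#'
#' @param observed,predicted numeric vectors of equal length >= 2.
#' @return a single number <= 1.
#' @export
#' @examples
#' goodness_of_fit(c(1, 2, 3), c(1, 2, 4)) # 0.5
goodness_of_fit <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  keep <- is.finite(observed) & is.finite(predicted)
  observed <- observed[keep]; predicted <- predicted[keep]
  ss_res <- sum((observed - predicted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    tol <- (mean(abs(observed)) + 1) * 1e-12
    return(if (ss_res <= tol^2 * length(observed)) 1 else 0)
  }
  1 - ss_res / ss_tot
}

#' Fit kinetic parameters to time-series data
#'
#' Minimizes the weighted sum of squared residuals over all experiments
#' simultaneously. Residuals are scaled by the relative measurement error
#' times the mean magnitude of each observable within each experiment, so
#' that cell counts (1e5-1e6) and metabolites (1-60) contribute comparably.
#' Optimization runs in log-parameter space under box constraints with a
#' bounded quasi-Newton method (`nlminb`) and multi-start: the first start is
#' `init`, the remaining starts are log-uniform perturbations of it.
#'
#' @param data a [ts_dataset()].
#' @param init initial [kinetic_params()] guess; also supplies the values of
#'   all parameters that are not freed.
#' @param free character vector of parameter names to estimate.
#' @param lower,upper named bounds on the free parameters (natural scale);
#'   default is `init/50` and `init*50`.
#' @param n_starts number of multi-starts (default 5).
#' @param seed seed for the start perturbations.
#' @param death_mode see [specific_death_rate()].
#' @param control passed to [stats::nlminb()].
#' @return an object of class `fit_result`: fitted `params`, the `free`
#'   names, final `objective`, per-observable `r_squared` (pooled over
#'   experiments), `residuals`, `convergence` code (0 = converged),
#'   `converged` flag, and the per-start objective values.
#' @export
fit_parameters <- function(data, init = kinetic_params(),
                           free = .default_free,
                           lower = NULL, upper = NULL,
                           n_starts = 5, seed = 1L,
                           death_mode = c("printed", "inverse"),
                           control = list(iter.max = 200, eval.max = 600)) {
  stopifnot(inherits(data, "ts_dataset"))
  death_mode <- match.arg(death_mode)
  init <- as_kinetic_params(init)
  if (!all(free %in% .param_names))
    stop("unknown parameter names in `free`")
  n_obs <- sum(vapply(data, function(e) nrow(e$observations), 0L))
  if (n_obs < 4) stop("need at least 4 observed time points")

  base <- as.numeric(init); names(base) <- .param_names
  lo <- if (is.null(lower)) base[free] / 50 else lower[free]
  hi <- if (is.null(upper)) base[free] * 50 else upper[free]
  if (any(lo <= 0)) stop("bounds must be positive")

  make_params <- function(theta_log) {
    p <- base
    p[free] <- exp(theta_log)
    structure(p, class = "kinetic_params")
  }
  objective <- function(theta_log) {
    r <- .wresiduals(data, make_params(theta_log), death_mode)
    if (is.null(r) || any(!is.finite(r))) return(1e12)
    sum(r^2)
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  starts <- matrix(rep(log(base[free]), n_starts), nrow = n_starts,
                   byrow = TRUE)
  if (n_starts > 1)
    starts[-1, ] <- starts[-1, ] +
      matrix(runif((n_starts - 1) * length(free), -0.7, 0.7),
             nrow = n_starts - 1)

  best <- NULL
  per_start <- numeric(n_starts)
  for (s in seq_len(n_starts)) {
    th0 <- pmin(pmax(starts[s, ], log(lo)), log(hi))
    ans <- stats::nlminb(th0, objective, lower = log(lo), upper = log(hi),
                         control = control)
    per_start[s] <- ans$objective
    if (is.null(best) || ans$objective < best$objective) best <- ans
  }

  fitted <- make_params(best$par)
  # pooled per-observable R^2 on the data used for fitting
  r2 <- list()
  pooled <- list()
  for (e in data) {
    sim <- simulate_batch(e$setup, fitted, t_grid = e$observations$time_h,
                          death_mode = death_mode)
    for (v in intersect(names(e$observations), .observables)) {
      keep <- is.finite(e$observations[[v]])
      pooled[[v]] <- rbind(pooled[[v]],
                           cbind(e$observations[[v]][keep], sim[[v]][keep]))
    }
  }
  for (v in names(pooled))
    r2[[v]] <- goodness_of_fit(pooled[[v]][, 1], pooled[[v]][, 2])

  structure(list(
    params = fitted, free = free, objective = best$objective,
    r_squared = unlist(r2),
    residuals = .wresiduals(data, fitted, death_mode),
    convergence = best$convergence,
    converged = best$convergence == 0,
    message = best$message,
    per_start_objective = per_start,
    death_mode = death_mode,
    bounds = list(lower = lo, upper = hi),
    init = init
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> objective =", format(x$objective, digits = 5),
      if (!x$converged) "(optimizer did not report convergence; best-so-far)",
      "\n")
  cat("free parameters:\n")
  print(signif(unclass(x$params)[x$free], 4))
  cat("R^2 per observable:\n")
  print(round(x$r_squared, 3))
  invisible(x)
}

#' Monte-Carlo parameter uncertainty
#'
#' Propagates measurement uncertainty into an empirical parameter
#' distribution. In the default `"refit"` mode each replicate multiplies
#' every observation (including the initial time point) by independent
#' `Normal(1, noise)` factors truncated at 0 and refits the free parameters
#' starting from the point estimate; the collected vectors form the
#' distribution. `"jitter"` mode skips refitting and perturbs the point
#' estimate directly — cheaper, but it does not reflect the model's
#' sensitivity structure.
#'
#' @param data the [ts_dataset()] used for fitting.
#' @param fit a [fit_parameters()] result.
#' @param n number of replicates (the reference workflow uses 1000).
#' @param noise relative perturbation (reference: 0.15).
#' @param seed integer seed; fixed seed gives identical distributions.
#' @param mode `"refit"` (default) or `"jitter"`.
#' @param control optimizer control for the replicate refits (kept loose:
#'   the refits start at the point estimate).
#' @return an object of class `param_distribution`: `samples` (data frame,
#'   one replicate per row, all sixteen parameters), `free`, `n_failed`,
#'   `quantiles` (5/25/50/75/95% per parameter).
#' @export
monte_carlo_uncertainty <- function(data, fit, n = 1000, noise = 0.15,
                                    seed = 1L, mode = c("refit", "jitter"),
                                    control = list(iter.max = 40,
                                                   eval.max = 150)) {
  stopifnot(inherits(fit, "fit_result"), n >= 2, noise > 0)
  mode <- match.arg(mode)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  free <- fit$free
  base <- as.numeric(fit$params); names(base) <- .param_names
  samples <- matrix(NA_real_, nrow = n, ncol = length(.param_names),
                    dimnames = list(NULL, .param_names))
  failed <- 0L

  if (mode == "jitter") {
    set.seed(substream_seed(seed, "jitter"))
    for (r in seq_len(n)) {
      p <- base
      fac <- pmax(rnorm(length(free), 1, noise), 1e-6)
      p[free] <- p[free] * fac
      samples[r, ] <- p
    }
  } else {
    stopifnot(inherits(data, "ts_dataset"))
    lo <- fit$bounds$lower; hi <- fit$bounds$upper
    th0 <- log(pmin(pmax(base[free], lo), hi))
    for (r in seq_len(n)) {
      set.seed(substream_seed(seed, paste0("mc", r)))
      pert <- lapply(data, function(e) {
        obs <- e$observations
        for (v in intersect(names(obs), .observables)) {
          f <- pmax(rnorm(nrow(obs), 1, noise), 0)
          obs[[v]] <- obs[[v]] * f
        }
        list(setup = e$setup, observations = obs, rel_error = e$rel_error)
      })
      pert <- ts_dataset(pert)
      objective <- function(theta_log) {
        p <- base
        p[free] <- exp(theta_log)
        rr <- .wresiduals(pert, structure(p, class = "kinetic_params"),
                          fit$death_mode)
        if (is.null(rr) || any(!is.finite(rr))) return(1e12)
        sum(rr^2)
      }
      ans <- tryCatch(
        stats::nlminb(th0, objective, lower = log(lo), upper = log(hi),
                      control = control),
        error = function(e) NULL)
      if (is.null(ans) || !is.finite(ans$objective) ||
          ans$objective >= 1e12) {
        failed <- failed + 1L
      } else {
        p <- base
        p[free] <- exp(ans$par)
        samples[r, ] <- p
      }
    }
    if (failed > 0.2 * n)
      stop("Monte-Carlo aborted: ", failed, " of ", n, " refits failed")
    samples <- samples[stats::complete.cases(samples), , drop = FALSE]
  }

  qs <- apply(samples, 2, quantile, probs = c(0.05, 0.25, 0.5, 0.75, 0.95))
  structure(list(samples = as.data.frame(samples), free = free,
                 n_failed = failed, mode = mode, noise = noise, seed = seed,
                 quantiles = qs),
            class = "param_distribution")
}

#' @export
print.param_distribution <- function(x, ...) {
  cat("<param_distribution> ", nrow(x$samples), " samples (mode = ", x$mode,
      ", noise = ", x$noise, ", failed = ", x$n_failed, ")\n", sep = "")
  print(signif(x$quantiles[, x$free, drop = FALSE], 4))
  invisible(x)
}
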