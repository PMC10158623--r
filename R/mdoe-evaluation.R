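# The core mDoE loop: simulate every design point under parameter
# uncertainty, summarize outcomes, scalarize with a desirability function,
# fit a response surface and recommend culture conditions.

#' Desirability specification
#'
#' Derringer-Suich-style scalarization of a (mean target, spread) pair:
#' a larger-is-better ramp between anchors `L` and `T` for the mean and a
#' smaller-is-better ramp between `S_max` and 0 for the 10-90% spread,
#' combined by geometric mean.
#'
#' @param L lower anchor: means at or below `L` score 0.
#' @param T_ target anchor: means at or above `T_` score 1 (`L < T_`).
#' @param S_max spread anchor: spreads at or above `S_max` score 0.
#' @param w_mean,w_spread positive weight exponents of the two ramps.
#' @return an object of class `desirability_spec`.
#' @export
desirability_spec <- function(L, T_, S_max, w_mean = 1, w_spread = 1) {
  stopifnot(is.finite(L), is.finite(T_), L < T_, S_max >= 0,
            w_mean > 0, w_spread > 0)
  structure(list(L = L, T_ = T_, S_max = S_max,
                 w_mean = w_mean, w_spread = w_spread),
            class = "desirability_spec")
}

#' Desirability of an outcome summary
#'
#' `d1 = clip((y - L)/(T - L), 0, 1)^w_mean`,
#' `d2 = clip((S_max - s)/S_max, 0, 1)^w_spread`, `D = sqrt(d1 * d2)`.
#' With `S_max = 0` the spread ramp degenerates to an indicator of zero
#' spread.
#'
#' @param mean_target vector of mean outcomes `y`.
#' @param spread vector of 10-90% quantile spreads `s`.
#' @param spec a [desirability_spec()].
#' @return desirability values in `[0, 1]`.
#' @export
#' @examples
#' sp <- desirability_spec(L = 0, T_ = 10, S_max = 4)
#' desirability(5, 0, sp) # sqrt(0.5)
desirability <- function(mean_target, spread, spec) {
  stopifnot(inherits(spec, "desirability_spec"))
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  d1 <- clip01((mean_target - spec$L) / (spec$T_ - spec$L))^spec$w_mean
  d2 <- if (spec$S_max > 0)
    clip01((spec$S_max - spread) / spec$S_max)^spec$w_spread
  else as.numeric(spread <= 0)
  sqrt(d1 * d2)
}

# build a culture setup for one design row from the template
.setup_from_row <- function(row, template) {
  culture_setup(
    c_MC = if ("c_MC" %in% names(row)) row[["c_MC"]] else template$c_MC,
    seed_density = template$seed_density,
    c_Glc = if ("c_Glc" %in% names(row)) row[["c_Glc"]] else template$c_Glc,
    c_Gln = if ("c_Gln" %in% names(row)) row[["c_Gln"]] else template$c_Gln,
    c_LS = template$c_LS, c_Lac = template$c_Lac, c_Amm = template$c_Amm,
    carrier = template$carrier, volume = template$volume)
}

#' Simulate a design under parameter uncertainty
#'
#' For every design row, builds the culture setup from the factor values
#' (`c_Glc`, `c_Gln`, `c_MC`; anything else comes from `setup_template`),
#' draws `n_sim` parameter vectors with replacement from the Monte-Carlo
#' distribution, simulates each batch and records the target metric
#' (maximum attached cells per cm^2 of carrier, or per mL).
#'
#' @param design a `doe_design`.
#' @param setup_template a [culture_setup()] supplying carrier, seed density
#'   and everything the factors do not set.
#' @param param_dist a [monte_carlo_uncertainty()] result (or a data frame
#'   of parameter samples).
#' @param n_sim simulations per design point (default 100).
#' @param seed integer seed; evaluation is deterministic under it.
#' @param metric `"per_cm2"` (default) or `"per_mL"`.
#' @param t_grid simulation grid (h).
#' @param death_mode see [specific_death_rate()].
#' @return an object of class `design_evaluation` with `points` (factors +
#'   `mean_target`, `q10`, `q90`, `spread = q90 - q10`, `rel_spread =
#'   spread/mean`, `n_failed`, `valid`), the raw `samples` matrix, and the
#'   generating design. Points with more than 50% failed simulations are
#'   marked invalid.
#' @export
simulate_design <- function(design, setup_template, param_dist, n_sim = 100,
                            seed = 1L, metric = c("per_cm2", "per_mL"),
                            t_grid = seq(0, 336, by = 4),
                            death_mode = "printed") {
  stopifnot(inherits(design, "doe_design"), n_sim >= 2)
  metric <- match.arg(metric)
  samples_df <- if (inherits(param_dist, "param_distribution"))
    param_dist$samples else as.data.frame(param_dist)
  stopifnot(nrow(samples_df) >= 1)
  runs <- design$natural
  out_samples <- matrix(NA_real_, nrow = nrow(runs), ncol = n_sim)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  for (r in seq_len(nrow(runs))) {
    set.seed(substream_seed(seed, paste0("point", r)))
    draw <- sample(nrow(samples_df), n_sim, replace = TRUE)
    setup <- .setup_from_row(runs[r, ], setup_template)
    for (s in seq_len(n_sim)) {
      p <- as_kinetic_params(unlist(samples_df[draw[s], ]))
      val <- tryCatch({
        tr <- simulate_batch(setup, p, t_grid = t_grid, rtol = 1e-6,
                             atol = 1e-8, death_mode = death_mode)
        m <- culture_metrics(tr, setup)
        if (metric == "per_cm2") m$X_max_per_cm2 else m$X_max_per_mL
      }, error = function(e) NA_real_)
      out_samples[r, s] <- val
    }
  }
  pts <- runs
  ok_frac <- rowMeans(is.finite(out_samples))
  pts$mean_target <- apply(out_samples, 1, mean, na.rm = TRUE)
  pts$q10 <- apply(out_samples, 1, quantile, probs = 0.1, na.rm = TRUE,
                   names = FALSE)
  pts$q90 <- apply(out_samples, 1, quantile, probs = 0.9, na.rm = TRUE,
                   names = FALSE)
  pts$spread <- pts$q90 - pts$q10
  pts$rel_spread <- pts$spread / pmax(pts$mean_target, .Machine$double.eps)
  pts$n_failed <- rowSums(!is.finite(out_samples))
  pts$valid <- ok_frac >= 0.5
  structure(list(points = pts, samples = out_samples, design = design,
                 metric = metric, n_sim = n_sim, seed = seed),
            class = "design_evaluation")
}

# self-scaling anchors: 5th/95th percentiles of the evaluated outcomes
.auto_spec <- function(means, spreads, w_mean = 1, w_spread = 1) {
  L <- quantile(means, 0.05, names = FALSE)
  T_ <- quantile(means, 0.95, names = FALSE)
  if (T_ - L < 1e-12 * (abs(T_) + 1)) {
    L <- min(means) - 1
    T_ <- max(means) + 1
  }
  S_max <- quantile(spreads, 0.95, names = FALSE)
  desirability_spec(L, T_, S_max, w_mean, w_spread)
}

#' Attach desirability to an evaluated design
#'
#' The variability entering the spread ramp is, by default, the *relative*
#' 10-90% spread (`spread/mean`): the target metric spans an order of
#' magnitude across the carrier-concentration range, so an absolute spread
#' penalty would systematically punish exactly the high-yield points whose
#' Monte-Carlo spread scales with their mean. `spread_type = "absolute"`
#' restores the raw `q90 - q10`.
#'
#' @param evaluation a [simulate_design()] result.
#' @param spec a [desirability_spec()]; if `NULL`, anchors self-scale to the
#'   5th/95th percentiles of this evaluation's outcomes.
#' @param spread_type `"relative"` (default) or `"absolute"`.
#' @return the evaluation with a `desirability` column and the spec stored.
#' @export
score_evaluation <- function(evaluation, spec = NULL,
                             spread_type = c("relative", "absolute")) {
  stopifnot(inherits(evaluation, "design_evaluation"))
  spread_type <- match.arg(spread_type)
  pts <- evaluation$points
  s <- if (spread_type == "relative") pts$rel_spread else pts$spread
  if (is.null(spec))
    spec <- .auto_spec(pts$mean_target[pts$valid], s[pts$valid])
  pts$desirability <- desirability(pts$mean_target, s, spec)
  pts$desirability[!pts$valid] <- NA_real_
  evaluation$points <- pts
  evaluation$spec <- spec
  evaluation$spread_type <- spread_type
  evaluation
}

#' Fit a quadratic response surface to desirability
#'
#' Ordinary least squares of the desirability scores on the full quadratic
#' model matrix in coded units. Predictions are clipped to `[0, 1]`.
#'
#' @param evaluation a scored [score_evaluation()] result.
#' @return an object of class `response_surface` with `coefficients` and a
#'   `predict_fun(coded_matrix)`.
#' @export
fit_response_surface <- function(evaluation) {
  stopifnot(inherits(evaluation, "design_evaluation"))
  pts <- evaluation$points
  if (is.null(pts$desirability))
    stop("evaluation has no desirability; run score_evaluation() first")
  keep <- pts$valid & is.finite(pts$desirability)
  X <- quadratic_model_matrix(evaluation$design$coded[keep, , drop = FALSE])
  if (nrow(X) < ncol(X))
    stop("design too small for a quadratic surface: ", nrow(X), " runs for ",
         ncol(X), " coefficients")
  fit <- stats::lm.fit(X, pts$desirability[keep])
  if (fit$rank < ncol(X))
    stop("rank-deficient design: quadratic surface not estimable (rank ",
         fit$rank, " < ", ncol(X), ")")
  beta <- fit$coefficients
  space <- evaluation$design$space
  predict_fun <- function(coded) {
    coded <- as.matrix(coded)
    colnames(coded) <- space$names
    pmin(pmax(drop(quadratic_model_matrix(coded) %*% beta), 0), 1)
  }
  structure(list(coefficients = beta, space = space,
                 predict_fun = predict_fun,
                 residuals = fit$residuals),
            class = "response_surface")
}

#' Recommend culture conditions from evaluated designs
#'
#' Fits a response surface per scored evaluation, grid-searches each surface
#' over the factor space, and returns the `top_k` per-design optima ranked
#' by predicted desirability, labelled with the generating design.
#'
#' @param evaluations a list of scored [score_evaluation()] results.
#' @param top_k number of recommendations to return.
#' @param grid_n grid resolution per factor (default 50).
#' @return a data frame: design label, the factor combination in natural
#'   units, predicted desirability.
#' @export
recommend_conditions <- function(evaluations, top_k = 2, grid_n = 50) {
  if (inherits(evaluations, "design_evaluation"))
    evaluations <- list(evaluations)
  evaluations <- Filter(function(e) any(e$points$valid), evaluations)
  if (length(evaluations) == 0) stop("no valid evaluated designs")
  rows <- list()
  for (ev in evaluations) {
    surf <- fit_response_surface(ev)
    space <- ev$design$space
    k <- length(space$names)
    grid <- as.matrix(expand.grid(
      rep(list(seq(-1, 1, length.out = grid_n)), k)))
    pred <- surf$predict_fun(grid)
    i <- which.max(pred)
    nat <- coded_to_natural(grid[i, , drop = FALSE], space)
    rec <- as.data.frame(nat)
    rec$design <- ev$design$type
    rec$predicted_desirability <- pred[i]
    rows[[length(rows) + 1]] <- rec
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$predicted_desirability), ]
  rownames(out) <- NULL
  utils::head(out, top_k)
}

#' Compare experimental designs in silico
#'
#' Simulates each design under the same parameter distribution, scores every
#' point with a shared (pooled, self-scaled) desirability so designs are
#' comparable, and tabulates run count, maximum desirability and its
#' location. Designs within `tol` of the best desirability are candidates;
#' among them, those at the minimum run count are flagged `preferred`.
#'
#' @param designs a named list of `doe_design` objects.
#' @param setup_template,param_dist,n_sim,seed,metric,t_grid,death_mode as
#'   in [simulate_design()].
#' @param spec optional shared [desirability_spec()]; default self-scales on
#'   the pooled outcomes of all designs.
#' @param spread_type see [score_evaluation()].
#' @param tol desirability tolerance for "as good as the best" (default
#'   0.05).
#' @return a list with `table` (one row per design) and `evaluations` (the
#'   scored evaluations, for downstream [recommend_conditions()]).
#' @export
compare_designs <- function(designs, setup_template, param_dist, n_sim = 100,
                            seed = 1L, metric = "per_cm2",
                            t_grid = seq(0, 336, by = 4),
                            death_mode = "printed", spec = NULL,
                            spread_type = "relative", tol = 0.05) {
  stopifnot(is.list(designs), length(designs) >= 2)
  if (is.null(names(designs)))
    names(designs) <- make.unique(vapply(designs, function(d) d$type, ""))
  # one shared substream: identical designs get identical evaluations
  eval_seed <- substream_seed(seed, "simulate")
  evals <- lapply(designs, function(d)
    simulate_design(d, setup_template, param_dist, n_sim = n_sim,
                    seed = eval_seed, metric = metric, t_grid = t_grid,
                    death_mode = death_mode))
  names(evals) <- names(designs)
  if (is.null(spec)) {
    means <- unlist(lapply(evals, function(e)
      e$points$mean_target[e$points$valid]))
    spreads <- unlist(lapply(evals, function(e)
      if (spread_type == "relative") e$points$rel_spread[e$points$valid]
      else e$points$spread[e$points$valid]))
    spec <- .auto_spec(means, spreads)
  }
  evals <- lapply(evals, score_evaluation, spec = spec,
                  spread_type = spread_type)
  tab <- do.call(rbind, lapply(names(evals), function(nm) {
    pts <- evals[[nm]]$points
    i <- which.max(pts$desirability)
    row <- data.frame(design = nm, n_runs = nrow(pts),
                      max_desirability = pts$desirability[i])
    for (f in evals[[nm]]$design$space$names)
      row[[paste0("argmax_", f)]] <- pts[[f]][i]
    row
  }))
  best <- max(tab$max_desirability)
  near <- tab$max_desirability >= best - tol
  tab$preferred <- near & tab$n_runs == min(tab$n_runs[near])
  rownames(tab) <- NULL
  list(table = tab, evaluations = evals, spec = spec)
}
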