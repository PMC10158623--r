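# End-to-end workflow: synthesize data, calibrate, quantify uncertainty,
# generate designs, evaluate them under uncertainty, recommend conditions.
# Configuration is a nested list, serializable as JSON.

#' Default workflow configuration
#'
#' A complete nested configuration for [run_workflow()]: the synthetic
#' ground truth (model parameters, carrier, 15% noise), the three-factor
#' space, the design roster, desk-scale calibration settings and the
#' evaluation stage. `mc_n` and `n_sim` default to 100 (desk scale);
#' production-scale uncertainty propagation per the reference workflow
#' uses 1000 Monte-Carlo replicates.
#'
#' @param seed global seed; every stochastic stage derives its own
#'   substream from it via [substream_seed()].
#' @return a nested list of class `workflow_config`.
#' @export
default_workflow_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    carrier = list(name = "Cytodex 3 (synthetic fixture)",
                   area_per_gram = 2700, max_area_density = 4.5e5),
    model = list(params = as.list(unclass(kinetic_params())),
                 death_mode = "printed"),
    synthesis = list(noise = 0.15,
                     sample_times = c(seq(0, 120, by = 24),
                                      seq(168, 336, by = 48))),
    factor_space = list(names = c("c_Glc", "c_Gln", "c_MC"),
                        lower = c(5, 2, 1), upper = c(60, 12, 20),
                        units = c("mmol/L", "mmol/L", "g/L")),
    designs = list(
      list(type = "ccd", center_replicates = 6),
      list(type = "bbd", center_replicates = 12),
      list(type = "lhs", n = 16),
      list(type = "d_optimal", n = 16),
      list(type = "i_optimal", n = 16),
      list(type = "lhsd_d_optimal", n = 16, n_lhs_candidates = 64)
    ),
    calibration = list(n_starts = 3, init_factor = 1.5,
                       mc_n = 100, mc_noise = 0.15, mc_mode = "refit"),
    evaluation = list(n_sim = 100, metric = "per_cm2", top_k = 2,
                      t_end = 336, dt = 4)
  ), class = "workflow_config")
}

#' Validate a workflow configuration
#'
#' Collects every violation (missing sections, bad bounds, non-positive
#' values) instead of stopping at the first; an empty return value means the
#' configuration is runnable.
#'
#' @param config a configuration list (see [default_workflow_config()]).
#' @return character vector of violations (length 0 if valid).
#' @export
validate_config <- function(config) {
  v <- character(0)
  need <- c("seed", "carrier", "model", "synthesis", "factor_space",
            "designs", "calibration", "evaluation")
  missing <- setdiff(need, names(config))
  if (length(missing) > 0)
    v <- c(v, paste0("missing section: ", missing))
  if ("carrier" %in% names(config)) {
    ca <- config$carrier
    if (is.null(ca$area_per_gram) || ca$area_per_gram <= 0)
      v <- c(v, "carrier: area_per_gram must be > 0")
    if (is.null(ca$max_area_density) || ca$max_area_density <= 0)
      v <- c(v, "carrier: max_area_density must be > 0")
  }
  if ("model" %in% names(config)) {
    p <- unlist(config$model$params)
    bad <- tryCatch({ as_kinetic_params(p); character(0) },
                    error = function(e) conditionMessage(e))
    v <- c(v, if (length(bad) > 0 && nzchar(bad[1]))
      paste0("model: ", bad) else character(0))
  }
  if ("synthesis" %in% names(config)) {
    if (is.null(config$synthesis$noise) || config$synthesis$noise < 0)
      v <- c(v, "synthesis: noise must be >= 0")
  }
  if ("factor_space" %in% names(config)) {
    fs <- config$factor_space
    if (length(fs$names) == 0) {
      v <- c(v, "factor_space: no factors defined")
    } else {
      bad <- which(fs$lower >= fs$upper)
      for (b in bad)
        v <- c(v, paste0("factor_space: lower >= upper for factor ",
                         fs$names[b]))
    }
  }
  if ("designs" %in% names(config) && length(config$designs) == 0)
    v <- c(v, "designs: design list is empty")
  if ("evaluation" %in% names(config)) {
    if (is.null(config$evaluation$n_sim) || config$evaluation$n_sim < 2)
      v <- c(v, "evaluation: n_sim must be >= 2")
  }
  v
}

.build_design <- function(spec, space, seed) {
  type <- spec$type
  switch(type,
    ccd = ccd(space, center_replicates = spec$center_replicates %||% 6),
    bbd = bbd(space, center_replicates = spec$center_replicates %||% 3),
    lhs = lhs_design(space, n = spec$n %||% 16,
                     seed = substream_seed(seed, "lhs")),
    d_optimal = d_optimal(space, n = spec$n %||% 16,
                          seed = substream_seed(seed, "dopt")),
    i_optimal = i_optimal(space, n = spec$n %||% 16,
                          seed = substream_seed(seed, "iopt")),
    lhsd_d_optimal = lhsd_plus_d_optimal(
      space, n = spec$n %||% 16,
      n_lhs_candidates = spec$n_lhs_candidates %||% 64,
      seed = substream_seed(seed, "lhsd")),
    stop("unknown design type: ", type))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full mDoE workflow
#'
#' Executes synth -> fit -> mc -> design -> evaluate -> recommend, writing
#' per-stage artifacts (all plain text) under `out_dir` and a summary JSON.
#' Identical config + seed give identical outputs. A stage failure stops
#' with a stage-labelled error; artifacts of completed stages remain on
#' disk.
#'
#' @param config a configuration list; see [default_workflow_config()].
#' @param out_dir output directory.
#' @param verbose print stage progress.
#' @return (invisibly) a list with the fitted result, parameter
#'   distribution, design comparison, recommendations and artifact paths.
#' @export
run_workflow <- function(config = default_workflow_config(),
                         out_dir = tempfile("mdoe_run_"), verbose = TRUE) {
  viol <- validate_config(config)
  if (length(viol) > 0)
    stop("invalid configuration:\n  ", paste(viol, collapse = "\n  "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  say <- function(...) if (verbose) message("[mdoe] ", ...)
  stage <- function(name, expr) {
    say("stage: ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  carrier <- carrier_spec(config$carrier$name %||% "carrier",
                          config$carrier$area_per_gram,
                          config$carrier$max_area_density)
  truth_params <- as_kinetic_params(unlist(config$model$params))
  death_mode <- config$model$death_mode %||% "printed"

  # --- synth ---------------------------------------------------------------
  sets <- stage("synth", {
    truth <- ground_truth(params = truth_params, carrier = carrier,
                          noise = config$synthesis$noise,
                          sample_times = unlist(config$synthesis$sample_times),
                          death_mode = death_mode)
    s <- generate_modeling_set(truth, seed = substream_seed(seed, "synth"))
    write_dataset(s$training, file.path(out_dir, "training"))
    write_dataset(s$verification, file.path(out_dir, "verification"))
    s
  })

  # --- fit -----------------------------------------------------------------
  fit <- stage("fit", {
    cal <- config$calibration
    init <- truth_params
    f <- cal$init_factor %||% 1.5
    init[.default_free] <- init[.default_free] * f
    init <- as_kinetic_params(unclass(init))
    res <- fit_parameters(sets$training, init = init,
                          n_starts = cal$n_starts %||% 3,
                          seed = substream_seed(seed, "fit"),
                          death_mode = death_mode)
    write.csv(data.frame(parameter = .param_names,
                         estimate = as.numeric(res$params)),
              file.path(out_dir, "fitted_parameters.csv"), row.names = FALSE)
    write.csv(data.frame(observable = names(res$r_squared),
                         r_squared = as.numeric(res$r_squared)),
              file.path(out_dir, "fit_r_squared.csv"), row.names = FALSE)
    res
  })

  # --- mc ------------------------------------------------------------------
  dist <- stage("mc", {
    cal <- config$calibration
    d <- monte_carlo_uncertainty(sets$training, fit, n = cal$mc_n %||% 100,
                                 noise = cal$mc_noise %||% 0.15,
                                 seed = substream_seed(seed, "mc"),
                                 mode = cal$mc_mode %||% "refit")
    write_param_samples(d, file.path(out_dir, "parameter_samples.csv"))
    d
  })

  # --- design --------------------------------------------------------------
  space <- factor_space(config$factor_space$names, config$factor_space$lower,
                        config$factor_space$upper, config$factor_space$units)
  designs <- stage("design", {
    ds <- lapply(config$designs, .build_design, space = space, seed = seed)
    names(ds) <- vapply(config$designs, function(s) s$type, "")
    dir.create(file.path(out_dir, "designs"), showWarnings = FALSE)
    for (nm in names(ds))
      write_design(ds[[nm]], file.path(out_dir, "designs",
                                       paste0(nm, ".csv")))
    ds
  })

  # --- evaluate ------------------------------------------------------------
  template <- culture_setup(c_MC = 10, seed_density = 6000, c_Glc = 25,
                            c_Gln = 4, carrier = carrier)
  cmp <- stage("evaluate", {
    ev <- config$evaluation
    res <- compare_designs(designs, template, dist,
                           n_sim = ev$n_sim %||% 100,
                           seed = substream_seed(seed, "evaluate"),
                           metric = ev$metric %||% "per_cm2",
                           t_grid = seq(0, ev$t_end %||% 336,
                                        by = ev$dt %||% 4),
                           death_mode = death_mode)
    write.csv(res$table, file.path(out_dir, "design_comparison.csv"),
              row.names = FALSE)
    res
  })

  # --- recommend -----------------------------------------------------------
  rec <- stage("recommend", {
    r <- recommend_conditions(cmp$evaluations,
                              top_k = config$evaluation$top_k %||% 2)
    write.csv(r, file.path(out_dir, "recommended_conditions.csv"),
              row.names = FALSE)
    r
  })

  summary <- list(
    seed = seed,
    config_hash = substream_seed(0, jsonlite::toJSON(unclass(config),
                                                     digits = NA,
                                                     auto_unbox = TRUE)),
    fit = list(objective = fit$objective,
               r_squared = as.list(round(fit$r_squared, 6))),
    mc = list(n = nrow(dist$samples), failed = dist$n_failed),
    best_design = cmp$table$design[which.max(cmp$table$max_desirability)],
    recommended = rec
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  say("done: ", out_dir)
  invisible(list(out_dir = out_dir, datasets = sets, fit = fit,
                 param_dist = dist, designs = designs, comparison = cmp,
                 recommended = rec))
}

#' Read / write a workflow configuration as JSON
#'
#' @param path JSON file path.
#' @param config a configuration list.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  # design list must stay a list of specs even after simplification
  if (is.data.frame(cfg$designs))
    cfg$designs <- lapply(seq_len(nrow(cfg$designs)), function(i)
      as.list(cfg$designs[i, !is.na(cfg$designs[i, ])]))
  structure(cfg, class = "workflow_config")
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
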