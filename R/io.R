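# Plain-text artifact formats: trajectories, datasets with manifest, and
# design files with a JSON metadata sidecar. Everything is diffable text.

.traj_units <- c(time_h = "h", X_t = "cells/mL", X_V = "cells/mL",
                 X_Sus = "cells/mL", c_Glc = "mmol/L", c_Gln = "mmol/L",
                 c_LS = "a.u./L", c_Lac = "mmol/L", c_Amm = "mmol/L")

#' Write / read a simulated trajectory as delimited text
#'
#' CSV with a leading `#`-comment line carrying the units.
#'
#' @param trajectory a data frame from [simulate_batch()].
#' @param path output file path.
#' @return `read_trajectory` returns a data frame.
#' @export
write_trajectory <- function(trajectory, path) {
  df <- as.data.frame(trajectory)
  con <- file(path, "w")
  on.exit(close(con))
  units <- .traj_units[names(df)]
  units[is.na(units)] <- ""
  writeLines(paste0("# units: ", paste(names(df), units, sep = "=",
                                       collapse = ", ")), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  read.csv(path, comment.char = "#")
}

#' Write / read a calibration dataset
#'
#' One CSV per experiment plus a `manifest.csv` holding every setup field,
#' the carrier properties and the relative measurement error.
#'
#' @param dataset a [ts_dataset()].
#' @param dir output directory (created if needed).
#' @return `read_dataset` returns a [ts_dataset()].
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "ts_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nms <- names(dataset)
  if (is.null(nms)) nms <- paste0("exp", seq_along(dataset))
  manifest <- do.call(rbind, lapply(seq_along(dataset), function(i) {
    e <- dataset[[i]]
    f <- paste0(nms[i], ".csv")
    write_trajectory(e$observations, file.path(dir, f))
    data.frame(name = nms[i], file = f, c_MC = e$setup$c_MC,
               seed_density = e$setup$seed_density, c_Glc = e$setup$c_Glc,
               c_Gln = e$setup$c_Gln, c_LS = e$setup$c_LS,
               c_Lac = e$setup$c_Lac, c_Amm = e$setup$c_Amm,
               volume = e$setup$volume, rel_error = e$rel_error,
               carrier = e$setup$carrier$name,
               area_per_gram = e$setup$carrier$area_per_gram,
               max_area_density = e$setup$carrier$max_area_density)
  }))
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  man <- read.csv(file.path(dir, "manifest.csv"))
  exps <- lapply(seq_len(nrow(man)), function(i) {
    m <- man[i, ]
    carrier <- carrier_spec(m$carrier, m$area_per_gram, m$max_area_density)
    setup <- culture_setup(c_MC = m$c_MC, seed_density = m$seed_density,
                           c_Glc = m$c_Glc, c_Gln = m$c_Gln, c_LS = m$c_LS,
                           c_Lac = m$c_Lac, c_Amm = m$c_Amm,
                           carrier = carrier, volume = m$volume)
    list(setup = setup,
         observations = read_trajectory(file.path(dir, m$file)),
         rel_error = m$rel_error)
  })
  names(exps) <- man$name
  ts_dataset(exps)
}

#' Write / read an experimental design
#'
#' Natural-unit runs as CSV (header carries the units) with a JSON sidecar
#' (`<path>.meta.json`) recording type, seed and generation settings.
#'
#' @param design a `doe_design`.
#' @param path CSV output path.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "doe_design"))
  con <- file(path, "w")
  writeLines(paste0("# units: ",
                    paste(design$space$names, design$space$units,
                          sep = "=", collapse = ", ")), con)
  write.csv(design$natural, con, row.names = FALSE)
  close(con)
  meta <- design$meta
  meta$trace <- NULL  # keep the sidecar small
  jsonlite::write_json(
    list(type = design$type, meta = meta,
         space = list(names = design$space$names, lower = design$space$lower,
                      upper = design$space$upper, units = design$space$units)),
    paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  runs <- read.csv(path, comment.char = "#")
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  space <- factor_space(meta$space$names, meta$space$lower, meta$space$upper,
                        meta$space$units)
  new_design(meta$type, natural_to_coded(runs, space), space,
             meta = as.list(meta$meta))
}

#' Write a parameter-sample table
#'
#' @param dist a [monte_carlo_uncertainty()] result.
#' @param path CSV output path (one replicate per row).
#' @export
write_param_samples <- function(dist, path) {
  stopifnot(inherits(dist, "param_distribution"))
  write.csv(dist$samples, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_param_samples
#' @export
read_param_samples <- function(path) {
  s <- read.csv(path)
  stopifnot(all(.param_names %in% names(s)))
  structure(list(samples = s[, .param_names], free = .param_names,
                 n_failed = 0L, mode = "file", noise = NA_real_,
                 seed = NA_integer_,
                 quantiles = apply(s[, .param_names], 2, quantile,
                                   probs = c(0.05, 0.25, 0.5, 0.75, 0.95))),
            class = "param_distribution")
}
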