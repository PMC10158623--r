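# Synthetic shake-flask experiments: a known ground truth plus multiplicative
# measurement noise, structured like the eight-experiment modelling grid.

#' Ground truth for synthetic experiment generation
#'
#' Bundles the kinetic parameters, carrier, noise level and sampling scheme
#' that define the simulated "world" from which synthetic shake-flask data
#' are drawn. Defaults: 15% relative measurement error, sampling every 24 h
#' up to 120 h and every 48 h thereafter, 336 h horizon.
#'
#' @param params a [kinetic_params()] vector (defaults to the documented
#'   fixture set).
#' @param carrier a [carrier_spec()].
#' @param noise relative measurement error (standard deviation of the
#'   multiplicative noise), >= 0.
#' @param sample_times sampling time points (h).
#' @param death_mode growth/death orientation, see [specific_death_rate()].
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(params = kinetic_params(),
                         carrier = cytodex3(),
                         noise = 0.15,
                         sample_times = c(seq(0, 120, by = 24),
                                          seq(168, 336, by = 48)),
                         death_mode = "printed") {
  params <- as_kinetic_params(params)
  stopifnot(inherits(carrier, "carrier_spec"), noise >= 0,
            length(sample_times) > 2, sample_times[1] == 0,
            all(diff(sample_times) > 0))
  structure(list(params = params, carrier = carrier, noise = noise,
                 sample_times = sample_times, death_mode = death_mode),
            class = "ground_truth")
}

#' The eight shake-flask setups of the modelling grid
#'
#' Initial microcarrier, glucose and glutamine concentrations of the eight
#' experiments used for model building (1-6) and verification (7-8), all
#' seeded at 6000 cells/cm^2.
#'
#' @param carrier a [carrier_spec()] shared by all setups.
#' @return a named list of eight [culture_setup()] objects
#'   (`exp1` ... `exp8`).
#' @export
#' @examples
#' setups <- table1_setups()
#' sapply(setups, function(s) s$c_MC)
table1_setups <- function(carrier = cytodex3()) {
  grid <- data.frame(
    c_MC = c(20, 20, 10, 10, 10, 5, 3, 1),
    c_Glc = c(30, 60, 5.6, 25, 60, 60, 25, 25),
    c_Gln = c(12, 12, 2, 12, 12, 12, 4, 4)
  )
  out <- lapply(seq_len(8), function(i)
    culture_setup(c_MC = grid$c_MC[i], seed_density = 6000,
                  c_Glc = grid$c_Glc[i], c_Gln = grid$c_Gln[i],
                  carrier = carrier))
  names(out) <- paste0("exp", 1:8)
  out
}

# observables emitted by the generator; c_LS is unobservable by definition
.observables <- c("X_t", "X_V", "X_Sus", "c_Glc", "c_Gln", "c_Lac", "c_Amm")

#' Generate one noisy synthetic experiment
#'
#' Simulates the ground-truth model for the given setup, samples it at the
#' configured cadence and applies independent multiplicative noise
#' `Normal(1, noise)` (truncated at 0) to every observation. The limiting
#' substrate is never emitted.
#'
#' @param setup a [culture_setup()].
#' @param truth a [ground_truth()].
#' @param seed integer seed for the noise draws.
#' @return a list with elements `setup`, `observations` (data frame with
#'   `time_h` and the observable columns), `rel_error` (scalar), and `seed`.
#' @export
generate_experiment <- function(setup, truth, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  tr <- simulate_batch(setup, truth$params, t_grid = truth$sample_times,
                       death_mode = truth$death_mode)
  obs <- as.data.frame(tr)[, c("time_h", .observables)]
  if (truth$noise > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    for (v in .observables) {
      f <- pmax(rnorm(nrow(obs), mean = 1, sd = truth$noise), 0)
      obs[[v]] <- obs[[v]] * f
    }
  }
  list(setup = setup, observations = obs, rel_error = max(truth$noise, 1e-6),
       seed = seed)
}

#' Generate the six-experiment modelling set plus the verification pair
#'
#' Experiments 1-6 of the grid become the training dataset, experiments 7-8
#' (the low-carrier verification cultures) are held out. Each experiment gets
#' its own noise substream derived from `seed`.
#'
#' @param truth a [ground_truth()].
#' @param seed integer master seed.
#' @return a list with `training` and `verification`, each a
#'   `ts_dataset` (list of experiments as in [generate_experiment()]).
#' @export
generate_modeling_set <- function(truth, seed = 1L) {
  setups <- table1_setups(truth$carrier)
  exps <- lapply(seq_along(setups), function(i)
    generate_experiment(setups[[i]], truth, seed = substream_seed(seed, i)))
  names(exps) <- names(setups)
  list(training = ts_dataset(exps[1:6]),
       verification = ts_dataset(exps[7:8]))
}

# save/restore .Random.seed so generators don't clobber the caller's RNG state
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Derive a reproducible substream seed
#'
#' Deterministically maps a master seed and a stage label (or index) to a
#' 31-bit seed, so that workflow stages and per-experiment noise draws are
#' independent yet reproducible from one global seed.
#'
#' @param seed master integer seed.
#' @param stage a string or integer identifying the substream.
#' @return an integer seed in `[0, 2^31)`.
#' @export
substream_seed <- function(seed, stage) {
  key <- paste0(seed, "/", stage)
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}
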