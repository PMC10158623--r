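# Rate laws and the batch ODE model. The scalar rate functions here are the
# reference (R-level) route; simulation goes through the compiled RK45 core,
# and the test suite cross-checks the two.

.state_names <- c("X_t", "X_V", "X_Sus", "c_Glc", "c_Gln", "c_LS",
                  "c_Lac", "c_Amm")

space_factor <- function(X_V, X_V_max) {
  if (X_V_max <= 0) return(0)
  min(max((X_V_max - X_V) / X_V_max, 0), 1)
}

#' Specific growth rate
#'
#' Monod kinetics in the unobserved limiting substrate, damped by the free
#' space remaining on the carrier surface:
#' `mu = mu_max * c_LS/(c_LS + K_S_LS) * (X_V_max - X_V)/X_V_max`.
#'
#' @param c_LS limiting substrate (a.u./L), >= 0.
#' @param X_V attached viable cells (cells/mL), 0 <= X_V <= X_V_max.
#' @param X_V_max carrying capacity (cells/mL); see [xv_max()].
#' @param params a [kinetic_params()] vector.
#' @return mu in 1/h, guaranteed within `[0, mu_max]`.
#' @export
specific_growth_rate <- function(c_LS, X_V, X_V_max, params) {
  stopifnot(c_LS >= 0)
  if (X_V_max <= 0)
    stop("degenerate setup: X_V_max = 0 (no carrier surface)")
  params[["mu_max"]] * c_LS / (c_LS + params[["K_S_LS"]]) *
    space_factor(X_V, X_V_max)
}

#' Specific death rate
#'
#' In the printed orientation the death rate rises with the limiting
#' substrate, `mu_d = mu_d_min + mu_d_max * c_LS/(c_LS + K_d_LS)`, and falls
#' to `mu_d_min` at depletion. Because that direction is biologically unusual,
#' `mode = "inverse"` swaps the Monod term for `K_d_LS/(c_LS + K_d_LS)` so
#' that death rises as the substrate runs out.
#'
#' @inheritParams specific_growth_rate
#' @param mode `"printed"` (default) or `"inverse"`.
#' @return mu_d in 1/h, within `[mu_d_min, mu_d_min + mu_d_max]`.
#' @export
specific_death_rate <- function(c_LS, params, mode = c("printed", "inverse")) {
  stopifnot(all(c_LS >= 0))
  mode <- match.arg(mode)
  frac <- if (mode == "printed") c_LS / (c_LS + params[["K_d_LS"]])
          else params[["K_d_LS"]] / (c_LS + params[["K_d_LS"]])
  params[["mu_d_min"]] + params[["mu_d_max"]] * frac
}

#' Attachment rate constant over time
#'
#' Suspension cells colonize free carrier surface only during the initial
#' attachment window: `k_att = k_att_max` for `t < t_att` and 0 afterwards
#' (right-closed: `t = t_att` gives 0).
#'
#' @param t time (h), vectorized.
#' @param params a [kinetic_params()] vector.
#' @return k_att in 1/h.
#' @export
attachment_rate <- function(t, params) {
  stopifnot(all(t >= 0))
  ifelse(t < params[["t_att"]], params[["k_att_max"]], 0)
}

#' Specific uptake rates of glucose, glutamine and limiting substrate
#'
#' Glucose and glutamine uptake are growth-coupled (`mu / yield`) with their
#' own Monod saturation, and carry the carrier-space factor a second time in
#' addition to the one inside `mu` — the model is implemented exactly as
#' printed. Limiting-substrate uptake is plain Monod, not growth-coupled.
#'
#' @param state named numeric state vector (see [simulate_batch()] columns).
#' @param X_V_max carrying capacity (cells/mL).
#' @param params a [kinetic_params()] vector.
#' @return named vector `c(q_Glc, q_Gln, q_LS)`; units are concentration
#'   per hour per (cell/mL).
#' @export
uptake_rates <- function(state, X_V_max, params) {
  sf <- space_factor(state[["X_V"]], X_V_max)
  mu <- if (X_V_max > 0)
    specific_growth_rate(max(state[["c_LS"]], 0), state[["X_V"]], X_V_max,
                         params)
  else 0
  glc <- max(state[["c_Glc"]], 0)
  gln <- max(state[["c_Gln"]], 0)
  ls <- max(state[["c_LS"]], 0)
  c(q_Glc = mu / params[["Y_X_Glc"]] * glc / (glc + params[["k_Glc"]]) * sf,
    q_Gln = mu / params[["Y_X_Gln"]] * gln / (gln + params[["k_Gln"]]) * sf,
    q_LS = params[["q_LS_max"]] * ls / (ls + params[["k_LS"]]))
}

#' Time derivatives of the batch model state
#'
#' Reference R implementation of the full right-hand side, composed from the
#' exported rate functions. The compiled integrator used by
#' [simulate_batch()] implements the same equations independently; the test
#' suite holds the two routes together.
#'
#' @param t time (h).
#' @param state named numeric vector with elements
#'   `X_t, X_V, X_Sus, c_Glc, c_Gln, c_LS, c_Lac, c_Amm`.
#' @param setup a [culture_setup()].
#' @param params a [kinetic_params()] vector.
#' @param death_mode passed to [specific_death_rate()].
#' @return named numeric vector of the eight time derivatives.
#' @export
derivatives <- function(t, state, setup, params,
                        death_mode = c("printed", "inverse")) {
  death_mode <- match.arg(death_mode)
  if (any(!is.finite(state))) stop("non-finite state")
  X_V_max <- xv_max(setup)
  sf <- space_factor(state[["X_V"]], X_V_max)
  mu <- if (X_V_max > 0)
    specific_growth_rate(max(state[["c_LS"]], 0), state[["X_V"]], X_V_max,
                         params)
  else 0
  mu_d <- specific_death_rate(max(state[["c_LS"]], 0), params, death_mode)
  q <- uptake_rates(state, X_V_max, params)
  k_att <- attachment_rate(t, params)
  att <- k_att * sf * state[["X_Sus"]]
  X_V <- state[["X_V"]]
  d <- c(
    X_t = mu * X_V - params[["K_Lys"]] * (state[["X_t"]] - X_V),
    X_V = (mu - mu_d) * X_V + att,
    X_Sus = mu_d * X_V - att,
    c_Glc = -q[["q_Glc"]] * X_V,
    c_Gln = -q[["q_Gln"]] * X_V,
    c_LS = -q[["q_LS"]] * X_V,
    c_Lac = params[["Y_Lac_Glc"]] * q[["q_Glc"]] * X_V,
    c_Amm = params[["Y_Amm_Gln"]] * q[["q_Gln"]] * X_V
  )
  d
}

#' Simulate a batch microcarrier culture
#'
#' Integrates the eight-state model with an adaptive Dormand-Prince 5(4)
#' scheme, segmenting the integration at the end of the attachment window so
#' the `k_att` switch never sits inside a step. The inoculum starts entirely
#' in suspension (`X_Sus(0) = seed_density * area`, `X_V(0) = 0`,
#' `X_t(0) = X_Sus(0)`), matching an overnight unattached seeding.
#'
#' @param setup a [culture_setup()].
#' @param params a [kinetic_params()] vector.
#' @param t_grid strictly increasing output times in hours, starting at 0.
#' @param rtol,atol integrator tolerances.
#' @param death_mode passed to [specific_death_rate()].
#' @return a `data.frame` of class `culture_trajectory` with columns
#'   `time_h` plus the eight states; the setup and parameters travel as
#'   attributes.
#' @export
#' @examples
#' s <- culture_setup(c_MC = 10, seed_density = 6000, c_Glc = 25, c_Gln = 12,
#'                    carrier = cytodex3())
#' tr <- simulate_batch(s, kinetic_params(), t_grid = seq(0, 240, by = 24))
#' culture_metrics(tr, s)
simulate_batch <- function(setup, params, t_grid = seq(0, 336, by = 4),
                           rtol = 1e-8, atol = 1e-10,
                           death_mode = c("printed", "inverse")) {
  stopifnot(inherits(setup, "culture_setup"))
  params <- as_kinetic_params(params)
  death_mode <- match.arg(death_mode)
  if (t_grid[1] != 0 || any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing and start at 0")
  x0 <- setup$seed_density * carrier_area(setup)
  y0 <- c(x0, 0, x0, setup$c_Glc, setup$c_Gln, setup$c_LS,
          setup$c_Lac, setup$c_Amm)
  m <- tryCatch(
    .simulate_cpp(y0, as.numeric(params), xv_max(setup), as.numeric(t_grid),
                  rtol, atol, death_mode == "inverse"),
    error = function(e) stop("integration failed for setup c_MC = ",
                             setup$c_MC, " g/L: ", conditionMessage(e),
                             call. = FALSE))
  out <- data.frame(time_h = t_grid, m)
  names(out) <- c("time_h", .state_names)
  attr(out, "setup") <- setup
  attr(out, "params") <- params
  class(out) <- c("culture_trajectory", "data.frame")
  out
}

#' Summary metrics of a culture trajectory
#'
#' The attached-cell maximum expressed per cm^2 of carrier surface, the first
#' time it is attained, the multiplication factor `VF = X_max/seed_density`
#' and population doublings `PD = log2(VF)`.
#'
#' @param trajectory a trajectory from [simulate_batch()] (or any data frame
#'   with `time_h` and `X_V` columns).
#' @param setup the [culture_setup()] the trajectory belongs to.
#' @return a list with `X_max_per_cm2`, `X_max_per_mL`, `t_at_max`, `VF`,
#'   `PD`.
#' @export
culture_metrics <- function(trajectory, setup) {
  stopifnot(inherits(setup, "culture_setup"), nrow(trajectory) > 0)
  if (setup$seed_density <= 0) stop("seed_density must be > 0")
  area <- carrier_area(setup)
  if (area <= 0) stop("no carrier surface in this setup")
  i <- which.max(trajectory$X_V)
  x_area <- trajectory$X_V[i] / area
  vf <- x_area / setup$seed_density
  list(X_max_per_cm2 = x_area,
       X_max_per_mL = trajectory$X_V[i],
       t_at_max = trajectory$time_h[i],
       VF = vf,
       PD = log2(vf))
}

#' @export
print.culture_trajectory <- function(x, ...) {
  s <- attr(x, "setup")
  cat("<culture_trajectory> ", nrow(x), " time points, 0-",
      max(x$time_h), " h", sep = "")
  if (!is.null(s)) cat(", c_MC = ", s$c_MC, " g/L", sep = "")
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("...\n")
  invisible(x)
}
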