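# Parameter container and validation for the microcarrier batch model.

.param_names <- c(
  "mu_max", "K_S_LS", "mu_d_min", "mu_d_max", "K_d_LS", "k_att_max",
  "t_att", "K_Lys", "Y_X_Glc", "k_Glc", "Y_X_Gln", "k_Gln",
  "q_LS_max", "k_LS", "Y_Lac_Glc", "Y_Amm_Gln"
)

#' Kinetic parameters of the microcarrier batch model
#'
#' Bundles every rate, saturation and yield constant of the growth,
#' attachment, death and metabolism kinetics into a named numeric vector of
#' class `kinetic_params`. The default values are the package's documented
#' synthetic ground truth: a plausible parameter set for an adherent
#' fibroblast-like line on a dextran microcarrier, tuned so that batch
#' trajectories peak between 144 and 216 h with growth terminated by
#' depletion of the unobserved limiting substrate while glucose and
#' glutamine remain in excess. They are fixture constants, not estimates.
#'
#' @param mu_max maximum specific growth rate (1/h).
#' @param K_S_LS limiting-substrate half-saturation for growth (a.u./L),
#'   on the scale where fresh medium has `c_LS = 1`.
#' @param mu_d_min minimum specific death rate (1/h).
#' @param mu_d_max maximum additional specific death rate (1/h).
#' @param K_d_LS limiting-substrate half-saturation for death (a.u./L).
#' @param k_att_max attachment rate constant during the attachment window
#'   (1/h).
#' @param t_att length of the attachment window (h); attachment stops at
#'   `t >= t_att`.
#' @param K_Lys lysis rate constant for dead cells (1/h).
#' @param Y_X_Glc cell yield on glucose (cells/mL per mmol/L).
#' @param k_Glc glucose half-saturation of uptake (mmol/L).
#' @param Y_X_Gln cell yield on glutamine (cells/mL per mmol/L).
#' @param k_Gln glutamine half-saturation of uptake (mmol/L).
#' @param q_LS_max maximum specific limiting-substrate uptake
#'   (a.u./L per (cell/mL) per h).
#' @param k_LS limiting-substrate uptake half-saturation (a.u./L).
#' @param Y_Lac_Glc lactate yield per glucose consumed (mmol/mmol).
#' @param Y_Amm_Gln ammonia yield per glutamine consumed (mmol/mmol).
#'
#' @return a named numeric vector of class `kinetic_params`.
#' @export
#' @examples
#' p <- kinetic_params()
#' p["mu_max"]
kinetic_params <- function(mu_max = 0.04,
                           K_S_LS = 0.08,
                           mu_d_min = 0.004,
                           mu_d_max = 0.015,
                           K_d_LS = 0.08,
                           k_att_max = 0.25,
                           t_att = 20,
                           K_Lys = 0.01,
                           Y_X_Glc = 4e5,
                           k_Glc = 0.5,
                           Y_X_Gln = 1e6,
                           k_Gln = 0.2,
                           q_LS_max = 1.4e-8,
                           k_LS = 0.05,
                           Y_Lac_Glc = 1.6,
                           Y_Amm_Gln = 0.7) {
  p <- c(mu_max = mu_max, K_S_LS = K_S_LS, mu_d_min = mu_d_min,
         mu_d_max = mu_d_max, K_d_LS = K_d_LS, k_att_max = k_att_max,
         t_att = t_att, K_Lys = K_Lys, Y_X_Glc = Y_X_Glc, k_Glc = k_Glc,
         Y_X_Gln = Y_X_Gln, k_Gln = k_Gln, q_LS_max = q_LS_max,
         k_LS = k_LS, Y_Lac_Glc = Y_Lac_Glc, Y_Amm_Gln = Y_Amm_Gln)
  validate_kinetic_params(p)
  structure(p, class = "kinetic_params")
}

#' @rdname kinetic_params
#' @param p a named numeric vector covering all sixteen parameters.
#' @export
as_kinetic_params <- function(p) {
  p <- unclass(p)
  if (!all(.param_names %in% names(p)))
    stop("missing kinetic parameters: ",
         paste(setdiff(.param_names, names(p)), collapse = ", "))
  p <- p[.param_names]
  validate_kinetic_params(p)
  structure(p, class = "kinetic_params")
}

validate_kinetic_params <- function(p) {
  if (any(!is.finite(p)))
    stop("kinetic parameters must be finite")
  strict <- setdiff(.param_names, "t_att")
  if (any(p[strict] <= 0))
    stop("kinetic parameters must be strictly positive: ",
         paste(strict[p[strict] <= 0], collapse = ", "))
  if (p[["t_att"]] < 0) stop("t_att must be >= 0")
  invisible(p)
}
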