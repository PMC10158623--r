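# Carrier specification, culture setup, and the carrying-capacity arithmetic.

#' Microcarrier specification
#'
#' Physical properties of a microcarrier type that determine the attachable
#' growth surface and the carrying capacity of a culture. Both surface area
#' and maximum areal cell density must be supplied explicitly; the package
#' never assumes them silently.
#'
#' @param name carrier identifier.
#' @param area_per_gram growth surface per gram of dry carrier (cm^2/g).
#' @param max_area_density maximum attachable cell density (cells/cm^2).
#' @return an object of class `carrier_spec`.
#' @export
carrier_spec <- function(name, area_per_gram, max_area_density) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(area_per_gram) || length(area_per_gram) != 1 ||
      !is.finite(area_per_gram) || area_per_gram <= 0)
    stop("area_per_gram must be a single positive number")
  if (!is.numeric(max_area_density) || length(max_area_density) != 1 ||
      !is.finite(max_area_density) || max_area_density <= 0)
    stop("max_area_density must be a single positive number")
  structure(list(name = name, area_per_gram = area_per_gram,
                 max_area_density = max_area_density),
            class = "carrier_spec")
}

#' @rdname carrier_spec
#' @details `cytodex3()` is a convenience constructor with
#'   literature-plausible values for a collagen-coated dextran carrier
#'   (2700 cm^2/g, 4.5e5 cells/cm^2 ceiling). It is a documented fixture for
#'   simulation studies, not a vendor datasheet.
#' @export
cytodex3 <- function() {
  carrier_spec("Cytodex 3 (synthetic fixture)",
               area_per_gram = 2700, max_area_density = 4.5e5)
}

#' Culture setup: carriers, inoculum and initial medium composition
#'
#' @param c_MC microcarrier concentration (g/L).
#' @param seed_density inoculum density (cells/cm^2 of carrier surface).
#' @param c_Glc,c_Gln initial glucose and glutamine (mmol/L).
#' @param c_LS initial limiting substrate (a.u./L); 1 corresponds to 100%
#'   fresh medium by normalization.
#' @param c_Lac,c_Amm initial lactate and ammonia (mmol/L).
#' @param carrier a [carrier_spec()].
#' @param volume working volume (mL); bookkeeping only, the model states are
#'   volumetric.
#' @return an object of class `culture_setup`.
#' @export
#' @examples
#' s <- culture_setup(c_MC = 10, seed_density = 6000, c_Glc = 25, c_Gln = 12,
#'                    carrier = cytodex3())
#' xv_max(s)
culture_setup <- function(c_MC, seed_density, c_Glc, c_Gln,
                          c_LS = 1, c_Lac = 0, c_Amm = 0,
                          carrier, volume = 40) {
  if (!inherits(carrier, "carrier_spec")) stop("carrier must be a carrier_spec")
  num1 <- function(x, nm, lo = 0) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lo)
      stop(nm, " must be a single number >= ", lo)
    x
  }
  structure(list(
    c_MC = num1(c_MC, "c_MC"), seed_density = num1(seed_density, "seed_density"),
    c_Glc = num1(c_Glc, "c_Glc"), c_Gln = num1(c_Gln, "c_Gln"),
    c_LS = num1(c_LS, "c_LS"), c_Lac = num1(c_Lac, "c_Lac"),
    c_Amm = num1(c_Amm, "c_Amm"), carrier = carrier,
    volume = { v <- num1(volume, "volume"); if (v <= 0) stop("volume must be > 0"); v }
  ), class = "culture_setup")
}

#' Carrier surface area per millilitre of culture
#'
#' @param setup a [culture_setup()].
#' @return surface area in cm^2 per mL.
#' @export
carrier_area <- function(setup) {
  stopifnot(inherits(setup, "culture_setup"))
  setup$c_MC * setup$carrier$area_per_gram / 1000
}

#' Carrying capacity of the carrier surface
#'
#' Maximum attached viable cell concentration supported by the carriers:
#' `c_MC * area_per_gram * max_area_density`, converted from per litre to
#' per millilitre of culture. Zero carriers give zero capacity.
#'
#' @param setup a [culture_setup()].
#' @return X_V,max in cells/mL.
#' @export
xv_max <- function(setup) {
  stopifnot(inherits(setup, "culture_setup"))
  carrier_area(setup) * setup$carrier$max_area_density
}
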