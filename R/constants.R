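#' Fractionation constants and physical parameters for the iWUE equation chain
#'
#' Builds the registry of isotopic fractionation factors and physical
#' constants used throughout the discrimination-to-iWUE calculations.
#' Defaults are the standard literature values for C3 and C4 leaf-level
#' carbon isotope discrimination.
#'
#' @param a CO2 diffusion fractionation in air, permil (default 4.4).
#' @param a_m Fractionation for diffusion across the mesophyll, permil
#'   (default 1.8).
#' @param b Rubisco carboxylation fractionation for C3 plants, permil
#'   (default 29).
#' @param f_prime Photorespiratory fractionation, permil (default 12;
#'   reported uncertainty +/- 4).
#' @param b3 Rubisco fractionation entering the C4 model, permil (default 30).
#' @param b4 Combined PEP carboxylase and upstream equilibrium fractionation,
#'   permil (default -5.7).
#' @param s Fractionation during CO2 leakage from bundle-sheath cells,
#'   permil (default 1.8).
#' @param phi Bundle-sheath leakiness, dimensionless in \[0, 1\]
#'   (default 0.21, a representative value for grasses under moderate
#'   conditions).
#' @param gsc_over_gm Ratio of stomatal to mesophyll conductance to CO2,
#'   dimensionless (default 0.79; reported uncertainty +/- 0.07).
#' @param gamma_star_25 CO2 compensation point in the absence of dark
#'   respiration at 25 degrees C and sea-level pressure, micromol/mol
#'   (default 42.75, a standard literature value; the source study does not
#'   print the value it used).
#' @param delta_ha Activation energy for the temperature response of the
#'   compensation point, J/mol (default 37830).
#' @param r_gas Universal gas constant, J/(mol K) (default 8.314).
#' @param p0 Sea-level atmospheric pressure, Pa (default 101325).
#' @param lapse_rate Temperature lapse rate of the standard-atmosphere
#'   barometric formula, K/m (default 0.0065).
#' @param t_ref Reference temperature of the barometric formula, K
#'   (default 288.15).
#' @param baro_exponent Exponent of the barometric formula
#'   (default 5.2561).
#'
#' @return A list of class `iwue_constants`.
#' @examples
#' k <- iwue_constants()
#' k$b - k$a
#' @export
iwue_constants <- function(a = 4.4, a_m = 1.8, b = 29, f_prime = 12,
                           b3 = 30, b4 = -5.7, s = 1.8, phi = 0.21,
                           gsc_over_gm = 0.79, gamma_star_25 = 42.75,
                           delta_ha = 37830, r_gas = 8.314, p0 = 101325,
                           lapse_rate = 0.0065, t_ref = 288.15,
                           baro_exponent = 5.2561) {
  if (phi < 0 || phi > 1) {
    stop("`phi` (bundle-sheath leakiness) must lie in [0, 1].", call. = FALSE)
  }
  if (p0 <= 0) stop("`p0` must be positive.", call. = FALSE)
  structure(
    list(
      a = a, a_m = a_m, b = b, f_prime = f_prime,
      b3 = b3, b4 = b4, s = s, phi = phi,
      gsc_over_gm = gsc_over_gm, gamma_star_25 = gamma_star_25,
      delta_ha = delta_ha, r_gas = r_gas, p0 = p0,
      lapse_rate = lapse_rate, t_ref = t_ref, baro_exponent = baro_exponent
    ),
    class = "iwue_constants"
  )
}

#' @export
print.iwue_constants <- function(x, ...) {
  cat("<iwue_constants>\n")
  cat(sprintf(
    "  C3: a = %.2f, a_m = %.2f, b = %.2f, f' = %.2f permil; gsc/gm = %.2f\n",
    x$a, x$a_m, x$b, x$f_prime, x$gsc_over_gm
  ))
  cat(sprintf(
    "  C4: b3 = %.2f, b4 = %.2f, s = %.2f permil; phi = %.2f\n",
    x$b3, x$b4, x$s, x$phi
  ))
  cat(sprintf(
    "  Gamma*25 = %.2f umol/mol, dHa = %g J/mol, R = %.3f, P0 = %g Pa\n",
    x$gamma_star_25, x$delta_ha, x$r_gas, x$p0
  ))
  invisible(x)
}

#' Atmospheric state for a set of elevations
#'
#' Derives atmospheric pressure and the partial pressure of CO2 for one or
#' more elevations, bundling them with the CO2 mole fraction and the carbon
#' isotope composition of air used downstream. The study region's growing
#' season (2021) motivates the defaults: a global-mean CO2 mole fraction of
#' 415 ppm and air delta-13C of -8.5 permil; both should be overridden when
#' better site values are known, and every downstream result records the
#' values used.
#'
#' @param elevation_m Elevation(s) above sea level, m.
#' @param temp_k Air temperature(s), K (recycled against elevation).
#' @param ca_ppm Atmospheric CO2 mole fraction, ppm.
#' @param d13c_air delta-13C of atmospheric CO2, permil vs PDB.
#' @param constants An [iwue_constants()] registry.
#'
#' @return A tibble with columns `elevation_m`, `temp_k`, `ca_ppm`,
#'   `d13c_air`, `patm_pa`, `p_ca_pa`.
#' @examples
#' atmospheric_state(c(0, 3800))
#' @export
atmospheric_state <- function(elevation_m, temp_k = 298.15, ca_ppm = 415,
                              d13c_air = -8.5,
                              constants = iwue_constants()) {
  patm <- barometric_pressure(elevation_m, constants)
  out <- tibble::tibble(
    elevation_m = elevation_m,
    temp_k = temp_k,
    ca_ppm = ca_ppm,
    d13c_air = d13c_air,
    patm_pa = patm,
    p_ca_pa = ca_ppm * 1e-6 * patm
  )
  if (any(out$temp_k <= 0)) stop("Temperatures must be positive kelvin.", call. = FALSE)
  out
}
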