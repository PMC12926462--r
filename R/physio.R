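#' Isotope ratio to delta notation
#'
#' Converts an isotope abundance ratio into delta notation relative to a
#' standard (permil).
#'
#' @param r_sample Isotope ratio of the sample (e.g. 13C/12C).
#' @param r_standard Isotope ratio of the reference standard (PDB for
#'   carbon, SMOW for oxygen).
#' @return Delta value in permil: `(r_sample / r_standard - 1) * 1000`.
#' @examples
#' ratio_to_delta(0.0111, 0.011180) # slightly depleted sample
#' @export
ratio_to_delta <- function(r_sample, r_standard) {
  if (any(r_sample <= 0) || any(r_standard <= 0)) {
    stop("Isotope ratios must be strictly positive.", call. = FALSE)
  }
  (r_sample / r_standard - 1) * 1000
}

#' Carbon isotope discrimination
#'
#' Fractionation between atmospheric CO2 and plant tissue,
#' `Delta = (delta_air - delta_plant) / (1 + delta_plant/1000)`, in permil.
#'
#' @param d13c_air delta-13C of atmospheric CO2, permil vs PDB.
#' @param d13c_plant delta-13C of the plant sample, permil vs PDB.
#' @return Discrimination Delta-13C in permil.
#' @seealso [d13c_from_discrimination()] for the inverse.
#' @examples
#' discrimination(-8.5, -30.07)
#' discrimination(-8.5, -13.72)
#' @export
discrimination <- function(d13c_air, d13c_plant) {
  if (any(d13c_plant <= -1000)) {
    stop("`d13c_plant` must exceed -1000 permil.", call. = FALSE)
  }
  (d13c_air - d13c_plant) / (1 + d13c_plant / 1000)
}

#' Plant delta-13C implied by a discrimination value
#'
#' Inverse of [discrimination()]: the leaf delta-13C that yields a given
#' Delta-13C under a given air composition.
#'
#' @param d13c_air delta-13C of atmospheric CO2, permil vs PDB.
#' @param delta13c Discrimination, permil.
#' @return Leaf delta-13C, permil vs PDB.
#' @export
d13c_from_discrimination <- function(d13c_air, delta13c) {
  (d13c_air - delta13c) / (1 + delta13c / 1000)
}

#' Barometric pressure as a function of elevation
#'
#' International-standard-atmosphere form
#' `P = P0 * (1 - L*z / T_ref)^k` with configurable lapse rate `L`,
#' reference temperature and exponent `k`. Monotonically decreasing in
#' elevation and equal to `P0` at sea level.
#'
#' @param elevation_m Elevation above sea level, m (>= -500).
#' @param constants An [iwue_constants()] registry.
#' @return Atmospheric pressure in Pa.
#' @examples
#' barometric_pressure(c(0, 1000, 3800))
#' @export
barometric_pressure <- function(elevation_m, constants = iwue_constants()) {
  if (any(elevation_m < -500)) {
    stop("Elevations below -500 m are not supported.", call. = FALSE)
  }
  k <- constants
  k$p0 * (1 - k$lapse_rate * elevation_m / k$t_ref)^k$baro_exponent
}

#' CO2 compensation point corrected for temperature and pressure
#'
#' Arrhenius temperature response scaled by the pressure ratio:
#' `Gamma* = Gamma*25 * (Patm/P0) * exp(dHa * (T - 298) / (R * T * 298))`.
#'
#' @param temp_k Leaf/air temperature, K.
#' @param patm_pa Atmospheric pressure, Pa.
#' @param constants An [iwue_constants()] registry.
#' @return Compensation point in micromol/mol.
#' @examples
#' gamma_star(298, 101325)            # exactly Gamma*25
#' gamma_star(288, barometric_pressure(2000))
#' @export
gamma_star <- function(temp_k, patm_pa, constants = iwue_constants()) {
  if (any(temp_k <= 0)) stop("`temp_k` must be positive.", call. = FALSE)
  if (any(patm_pa <= 0)) stop("`patm_pa` must be positive.", call. = FALSE)
  k <- constants
  k$gamma_star_25 * (patm_pa / k$p0) *
    exp(k$delta_ha * (temp_k - 298) / (k$r_gas * temp_k * 298))
}

# Photorespiratory correction term f' * Gamma*/pCa, dimensionless on the
# permil scale. Gamma* (umol/mol) is converted to a partial pressure via
# Patm before dividing by pCa = Ca * 1e-6 * Patm; Patm cancels in the
# ratio, so pressure enters only through Gamma* itself (which carries a
# Patm/P0 factor).
photoresp_term <- function(gamma_star_umol, ca_ppm, f_prime) {
  f_prime * gamma_star_umol / ca_ppm
}

photoresp_sign_value <- function(photoresp_sign) {
  photoresp_sign <- match.arg(photoresp_sign, c("model", "printed"))
  if (photoresp_sign == "model") 1 else -1
}

## ---- Inversions: Delta-13C -> intercellular / chloroplast CO2 ----------

#' Intercellular CO2 from discrimination, simple C3 model
#'
#' `Ci = Ca * (Delta - a) / (b - a)`.
#'
#' @param delta13c Discrimination, permil.
#' @param ca_ppm Atmospheric CO2 mole fraction, ppm.
#' @param constants An [iwue_constants()] registry.
#' @return Ci in ppm.
#' @examples
#' ci_simple_c3(22.239, 415)
#' @export
ci_simple_c3 <- function(delta13c, ca_ppm, constants = iwue_constants()) {
  k <- constants
  if (k$b == k$a) stop("Degenerate constants: b must differ from a.", call. = FALSE)
  ca_ppm * (delta13c - k$a) / (k$b - k$a)
}

#' Intercellular CO2 from discrimination with photorespiration, C3
#'
#' Simple C3 inversion augmented by the photorespiratory correction
#' `f' * Gamma*/pCa`. The default (`photoresp_sign = "model"`) inverts the
#' forward model `Delta = a + (b - a) Ci/Ca - f' Gamma*/pCa`, so the
#' correction term adds when solving for Ci;
#' `photoresp_sign = "printed"` subtracts it instead (the sign as commonly
#' typeset). Reduces exactly to [ci_simple_c3()] when `f' = 0` or
#' `Gamma* = 0`.
#'
#' @inheritParams ci_simple_c3
#' @param gamma_star_umol Compensation point from [gamma_star()], micromol/mol.
#' @param p_ca_pa Partial pressure of atmospheric CO2, Pa (must be > 0).
#' @param photoresp_sign `"model"` (default) or `"printed"`; see Details.
#' @return Ci in ppm.
#' @export
ci_photoresp_c3 <- function(delta13c, ca_ppm, gamma_star_umol, p_ca_pa,
                            constants = iwue_constants(),
                            photoresp_sign = c("model", "printed")) {
  k <- constants
  if (k$b == k$a) stop("Degenerate constants: b must differ from a.", call. = FALSE)
  if (any(p_ca_pa <= 0)) stop("`p_ca_pa` must be positive.", call. = FALSE)
  sgn <- photoresp_sign_value(photoresp_sign)
  term <- photoresp_term(gamma_star_umol, ca_ppm, k$f_prime)
  ca_ppm * (delta13c - k$a + sgn * term) / (k$b - k$a)
}

#' Chloroplast CO2 from discrimination, mesophyll C3 model
#'
#' Inverts the discrimination model that resolves the CO2 drawdown from
#' the intercellular space to the chloroplast,
#' `Delta = a + (b - a) Ci/Ca - (gsc/gm)(b - a_m)(Ca - Ci)/Ca - f' Gamma*/pCa`,
#' for the intercellular Ci, and then applies the mesophyll drawdown
#' `Cc = Ci - (gsc/gm)(Ca - Ci)` (from `A = gsc (Ca - Ci)` and
#' `Ci - Cc = A/gm`). As `gsc/gm -> 0` the result converges exactly to
#' [ci_photoresp_c3()]; for `gsc/gm > 0` the chloroplast value lies strictly
#' below the formulation's own intercellular value.
#'
#' @inheritParams ci_photoresp_c3
#' @return Cc in ppm. The intermediate intercellular value is attached as
#'   attribute `"ci_ppm"` (and is returned alongside by [compute_iwue()]).
#' @export
cc_mesophyll_c3 <- function(delta13c, ca_ppm, gamma_star_umol, p_ca_pa,
                            constants = iwue_constants(),
                            photoresp_sign = c("model", "printed")) {
  k <- constants
  r <- k$gsc_over_gm
  denom <- (k$b - k$a) + r * (k$b - k$a_m)
  if (abs(denom) < sqrt(.Machine$double.eps)) {
    stop("Degenerate constants: inversion denominator is zero.", call. = FALSE)
  }
  if (any(p_ca_pa <= 0)) stop("`p_ca_pa` must be positive.", call. = FALSE)
  sgn <- photoresp_sign_value(photoresp_sign)
  term <- photoresp_term(gamma_star_umol, ca_ppm, k$f_prime)
  ci <- ca_ppm * (delta13c - k$a + sgn * term + r * (k$b - k$a_m)) / denom
  cc <- ci - r * (ca_ppm - ci)
  attr(cc, "ci_ppm") <- ci
  cc
}

#' Intercellular CO2 from discrimination, C4 model
#'
#' Inverts the C4 discrimination model
#' `Delta = a + (b4 + (b3 - s) * phi - a) * Ci/Ca` for Ci. With default
#' constants the bracketed slope is negative, so valid discriminations lie
#' in `[a + slope, a]` = `[0.222, 4.4]` permil; values outside imply
#' `Ci/Ca` outside `[0, 1]`. The result is never clamped: out-of-range
#' values are flagged downstream by [compute_iwue()].
#'
#' @inheritParams ci_simple_c3
#' @return Ci in ppm.
#' @examples
#' ci_c4(3.0, 415)
#' @export
ci_c4 <- function(delta13c, ca_ppm, constants = iwue_constants()) {
  k <- constants
  slope <- k$b4 + (k$b3 - k$s) * k$phi - k$a
  if (abs(slope) < sqrt(.Machine$double.eps)) {
    stop("Degenerate constants: C4 discrimination slope is zero.", call. = FALSE)
  }
  ca_ppm * (delta13c - k$a) / slope
}

## ---- Forward models: CO2 -> Delta-13C ----------------------------------

#' Forward discrimination models
#'
#' Predict Delta-13C from an intercellular (or chloroplast) CO2 mole
#' fraction. These are the exact inverses of [ci_simple_c3()],
#' [ci_photoresp_c3()], [cc_mesophyll_c3()] and [ci_c4()]; the synthetic
#' transect generator uses them to translate a true iWUE into a leaf
#' delta-13C.
#'
#' @param ci_ppm,cc_ppm Intercellular / chloroplast CO2 mole fraction, ppm.
#' @inheritParams ci_photoresp_c3
#' @return Delta-13C in permil.
#' @name forward-discrimination
NULL

#' @rdname forward-discrimination
#' @export
delta_simple_c3 <- function(ci_ppm, ca_ppm, constants = iwue_constants()) {
  k <- constants
  k$a + (k$b - k$a) * ci_ppm / ca_ppm
}

#' @rdname forward-discrimination
#' @export
delta_photoresp_c3 <- function(ci_ppm, ca_ppm, gamma_star_umol, p_ca_pa,
                               constants = iwue_constants(),
                               photoresp_sign = c("model", "printed")) {
  k <- constants
  sgn <- photoresp_sign_value(photoresp_sign)
  term <- photoresp_term(gamma_star_umol, ca_ppm, k$f_prime)
  k$a + (k$b - k$a) * ci_ppm / ca_ppm - sgn * term
}

#' @rdname forward-discrimination
#' @export
delta_mesophyll_c3 <- function(cc_ppm, ca_ppm, gamma_star_umol, p_ca_pa,
                               constants = iwue_constants(),
                               photoresp_sign = c("model", "printed")) {
  k <- constants
  r <- k$gsc_over_gm
  sgn <- photoresp_sign_value(photoresp_sign)
  ci <- (cc_ppm + r * ca_ppm) / (1 + r)
  term <- photoresp_term(gamma_star_umol, ca_ppm, k$f_prime)
  k$a + (k$b - k$a) * ci / ca_ppm -
    r * (k$b - k$a_m) * (ca_ppm - ci) / ca_ppm - sgn * term
}

#' @rdname forward-discrimination
#' @export
delta_c4 <- function(ci_ppm, ca_ppm, constants = iwue_constants()) {
  k <- constants
  k$a + (k$b4 + (k$b3 - k$s) * k$phi - k$a) * ci_ppm / ca_ppm
}

#' Intrinsic water-use efficiency from CO2 mole fractions
#'
#' `iWUE = (Ca - Ci) / 1.6` in micromol CO2 per mol H2O; 1.6 is the ratio
#' of the diffusivities of water vapour and CO2 in air. Strictly
#' decreasing in Ci at fixed Ca.
#'
#' @param ca_ppm Atmospheric CO2 mole fraction, ppm.
#' @param ci_ppm Intercellular (or, for the mesophyll formulation,
#'   chloroplast) CO2 mole fraction, ppm.
#' @return iWUE in micromol CO2 / mol H2O.
#' @examples
#' iwue(415, 300.96)
#' @export
iwue <- function(ca_ppm, ci_ppm) {
  (ca_ppm - ci_ppm) / 1.6
}

#' Inverse of [iwue()]: the Ci implied by an iWUE at a given Ca.
#' @inheritParams iwue
#' @param iwue_value iWUE, micromol CO2 / mol H2O.
#' @return Ci in ppm.
#' @export
ci_from_iwue <- function(ca_ppm, iwue_value) {
  ca_ppm - 1.6 * iwue_value
}

## ---- Batch chain --------------------------------------------------------

#' Compute iWUE for a table of leaf isotope samples
#'
#' Runs the full equation chain per row: discrimination from leaf
#' delta-13C, barometric pressure from elevation, the temperature- and
#' pressure-corrected compensation point (for the formulations that need
#' it), inversion to Ci (or Cc), and iWUE. C3 rows use the requested
#' formulation; C4 rows always use the bundle-sheath leakiness model.
#' Rows whose implied `Ci/Ca` falls outside `[0, 1]` are flagged
#' (`in_range = FALSE`) with a warning and retained by default — never
#' silently clamped.
#'
#' @param data A data frame with at least `d13c_leaf` and `pathway`
#'   (`"C3"`/`"C4"`) columns; `elevation_m` is required (pressure), and the
#'   temperature column (default `mat_c`, degrees C) is required for the
#'   `photoresp` and `mesophyll` formulations.
#' @param formulation C3 formulation: `"simple"`, `"photoresp"` or
#'   `"mesophyll"`. Passing `"c4"` is only valid when every row is C4.
#' @param constants An [iwue_constants()] registry.
#' @param ca_ppm Atmospheric CO2 mole fraction, ppm (recorded in the output).
#' @param d13c_air delta-13C of atmospheric CO2, permil (recorded in the
#'   output).
#' @param temp_col Name of the temperature column (degrees C) used in the
#'   compensation-point correction.
#' @param photoresp_sign See [ci_photoresp_c3()].
#' @param drop_out_of_range If `TRUE`, rows with `Ci/Ca` outside `[0, 1]`
#'   are removed (with a message) instead of retained.
#'
#' @return The input tibble with appended columns `patm_pa`, `p_ca_pa`,
#'   `gamma_star_umol` (NA for formulations that do not use it),
#'   `delta13c`, `ci_ppm`, `cc_ppm` (mesophyll only), `ci_over_ca`,
#'   `iwue`, `in_range`, `formulation`, `ca_ppm`, `d13c_air`. For the
#'   mesophyll formulation iWUE is computed from the chloroplast value.
#' @examples
#' tbl <- tibble::tibble(
#'   d13c_leaf = c(-30.07, -26.5), pathway = "C3",
#'   elevation_m = c(40, 3000), mat_c = c(23, 9)
#' )
#' compute_iwue(tbl, formulation = "simple")
#' @export
compute_iwue <- function(data,
                         formulation = c("simple", "photoresp", "mesophyll", "c4"),
                         constants = iwue_constants(),
                         ca_ppm = 415, d13c_air = -8.5,
                         temp_col = "mat_c",
                         photoresp_sign = c("model", "printed"),
                         drop_out_of_range = FALSE) {
  formulation <- match.arg(formulation)
  stopifnot(is.data.frame(data))
  needed <- c("d13c_leaf", "pathway", "elevation_m")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    stop("Missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  pathway <- as.character(data$pathway)
  if (!all(pathway %in% c("C3", "C4"))) {
    stop("`pathway` must be 'C3' or 'C4' for every row.", call. = FALSE)
  }
  if (formulation == "c4" && any(pathway == "C3")) {
    stop("Formulation 'c4' is incompatible with C3 rows; ",
         "choose a C3 formulation for mixed tables.", call. = FALSE)
  }
  d13c <- data$d13c_leaf
  if (any(d13c < -40 | d13c > -5, na.rm = TRUE)) {
    warning("Some leaf delta-13C values fall outside the plausible ",
            "[-40, -5] permil range.", call. = FALSE)
  }

  k <- constants
  patm <- barometric_pressure(data$elevation_m, k)
  p_ca <- ca_ppm * 1e-6 * patm
  delta <- discrimination(d13c_air, d13c)

  needs_gs <- formulation %in% c("photoresp", "mesophyll")
  gs <- rep(NA_real_, nrow(data))
  if (needs_gs) {
    if (!temp_col %in% names(data)) {
      stop("Formulation '", formulation, "' needs temperature column `",
           temp_col, "`.", call. = FALSE)
    }
    gs <- gamma_star(data[[temp_col]] + 273.15, patm, k)
  }

  ci <- rep(NA_real_, nrow(data))
  cc <- rep(NA_real_, nrow(data))
  is_c4 <- pathway == "C4"
  form_tag <- ifelse(is_c4, "c4", formulation)

  if (any(!is_c4)) {
    i <- !is_c4
    ci[i] <- switch(formulation,
      simple = ci_simple_c3(delta[i], ca_ppm, k),
      photoresp = ci_photoresp_c3(delta[i], ca_ppm, gs[i], p_ca[i], k,
                                  photoresp_sign),
      mesophyll = {
        res <- cc_mesophyll_c3(delta[i], ca_ppm, gs[i], p_ca[i], k,
                               photoresp_sign)
        cc[i] <- as.numeric(res)
        attr(res, "ci_ppm")
      }
    )
  }
  if (any(is_c4)) ci[is_c4] <- ci_c4(delta[is_c4], ca_ppm, k)

  # the concentration entering iWUE: chloroplast for mesophyll C3 rows
  c_used <- ifelse(!is_c4 & formulation == "mesophyll", cc, ci)
  ratio <- c_used / ca_ppm
  in_range <- ratio >= 0 & ratio <= 1 & (ci / ca_ppm) >= 0 & (ci / ca_ppm) <= 1

  out <- dplyr::mutate(
    tibble::as_tibble(data),
    patm_pa = patm, p_ca_pa = p_ca, gamma_star_umol = gs,
    delta13c = delta, ci_ppm = ci, cc_ppm = cc,
    ci_over_ca = ratio,
    iwue = iwue(ca_ppm, c_used),
    in_range = in_range,
    formulation = form_tag,
    ca_ppm = ca_ppm, d13c_air = d13c_air
  )

  n_bad <- sum(!out$in_range, na.rm = TRUE)
  if (n_bad > 0) {
    warning(n_bad, " sample(s) imply Ci/Ca outside [0, 1]; flagged with ",
            "`in_range = FALSE`", if (drop_out_of_range) " and dropped",
            ".", call. = FALSE)
    if (drop_out_of_range) out <- dplyr::filter(out, .data$in_range)
  }
  out
}
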