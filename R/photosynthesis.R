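#' Michaelis constants and CO2 compensation point at leaf temperature
#'
#' Arrhenius scaling of `Kc`, `Ko` and `Gamma_star` from their 25 degC
#' references.
#'
#' @param T_LK Leaf temperature (K), in (273, 333).
#' @param params A [photo_params()] object.
#' @return List with `Kc`, `Ko`, `Gamma_star` (mol mol^-1).
#' @export
kinetics_at_T <- function(T_LK, params = photo_params(Vcmax25 = 50e-6)) {
  if (any(T_LK <= 273 | T_LK >= 333)) {
    stop("T_LK outside the supported kinetic range (273, 333) K")
  }
  list(Kc = arrhenius(params$Kc25, params$Ea_Kc, T_LK),
       Ko = arrhenius(params$Ko25, params$Ea_Ko, T_LK),
       Gamma_star = arrhenius(params$Gamma_star25, params$Ea_Gamma_star,
                              T_LK))
}

#' Photosynthetic capacity at leaf temperature
#'
#' Plain Arrhenius scaling, or the peaked (deactivating) form with a
#' thermal optimum when `peaked = TRUE`.
#'
#' @param cap25 Capacity at 25 degC (mol m^-2 s^-1).
#' @param T_LK Leaf temperature (K).
#' @param peaked Use the peaked deactivation form?
#' @param Ea Activation energy (J mol^-1).
#' @param Hd Deactivation energy (J mol^-1).
#' @param dS Entropy term (J mol^-1 K^-1).
#' @return Capacity at `T_LK` (mol m^-2 s^-1).
#' @export
capacity_at_T <- function(cap25, T_LK, peaked = FALSE, Ea = 65330,
                          Hd = 2e5, dS = 640) {
  base <- arrhenius(cap25, Ea, T_LK)
  if (!peaked) return(base)
  R <- 8.314
  base * (1 + exp((298.15 * dS - Hd) / (298.15 * R))) /
    (1 + exp((T_LK * dS - Hd) / (T_LK * R)))
}

#' Sigmoidal water-stress downregulation of photosynthetic capacity
#'
#' `(1 + exp(sf * psi_f)) / (1 + exp(sf * (psi_f - psi_L)))`: equal to 1
#' at `psi_L = 0`, about 0.5 at `psi_L = psi_f`, and declining toward 0
#' as the leaf water potential falls.
#'
#' @param psi_L Leaf water potential (MPa, <= 0).
#' @param sf Sensitivity (MPa^-1).
#' @param psi_f Inflection water potential (MPa).
#' @return Multiplier in (0, 1].
#' @export
water_stress_factor <- function(psi_L, sf, psi_f) {
  if (any(psi_L > 1e-12)) stop("psi_L must be <= 0")
  (1 + exp(sf * psi_f)) / (1 + exp(sf * (psi_f - psi_L)))
}

#' Electron transport rate from the non-rectangular hyperbola
#'
#' Lower root of
#' `curvature * J^2 - (yield * PPFD + Jmax) * J + yield * PPFD * Jmax = 0`.
#'
#' @param PPFD Photon flux (mol m^-2 s^-1, >= 0).
#' @param Jmax_at_T Maximum electron transport at leaf temperature
#'   (mol m^-2 s^-1).
#' @param quantum_yield Apparent quantum yield (mol electrons per mol
#'   photons).
#' @param curvature Curvature parameter in (0, 1).
#' @return Electron transport rate J (mol m^-2 s^-1).
#' @export
electron_transport <- function(PPFD, Jmax_at_T, quantum_yield = 0.28,
                               curvature = 0.9) {
  if (any(PPFD < 0)) stop("PPFD must be non-negative")
  a <- quantum_yield * PPFD
  b <- Jmax_at_T
  (a + b - sqrt((a + b)^2 - 4 * curvature * a * b)) / (2 * curvature)
}

#' Temperature- and stress-resolved photosynthesis branches
#'
#' Assembles the generic-model coefficients
#' `An = f0 * (ci - Gamma_star) / (ci + gamma) - Rd` for the
#' carboxylation branch (`f0 = Vcmax`, `gamma = Kc * (1 + oi / Ko)`) and
#' the electron-transport branch (`f0 = J / 4`, `gamma = 2 * Gamma_star`)
#' at the given leaf temperature, light level and (optionally) water
#' stress.
#'
#' @param params A [photo_params()] object.
#' @param T_LK Leaf temperature (K).
#' @param PPFD Photon flux (mol m^-2 s^-1).
#' @param psi_L Leaf water potential (MPa); the sigmoidal stress factor
#'   multiplies both capacities.  Use `NULL` (default) to skip the
#'   stress response, as when capacities were estimated independently.
#' @param peaked Use the peaked capacity-temperature response?
#' @return Object of class `photo_at_T`: list of two branch lists
#'   (`carboxylation`, `electron_transport`), each with `f0`, `gamma`,
#'   plus shared `Gamma_star` and `Rd`.
#' @export
photo_at_T <- function(params, T_LK, PPFD, psi_L = NULL, peaked = FALSE) {
  kin <- kinetics_at_T(T_LK, params)
  Vc <- capacity_at_T(params$Vcmax25, T_LK, peaked = peaked,
                      Ea = params$Ea_Vcmax, Hd = params$Hd,
                      dS = params$dS_Vcmax)
  Jm <- capacity_at_T(params$Jmax25, T_LK, peaked = peaked,
                      Ea = params$Ea_Jmax, Hd = params$Hd,
                      dS = params$dS_Jmax)
  if (!is.null(psi_L)) {
    fw <- water_stress_factor(psi_L, params$sf, params$psi_f)
    Vc <- Vc * fw
    Jm <- Jm * fw
  }
  J <- electron_transport(PPFD, Jm, params$quantum_yield, params$curvature)
  Rd <- arrhenius(params$Rd25, params$Ea_Rd, T_LK)
  structure(list(
    carboxylation = list(f0 = Vc, gamma = kin$Kc * (1 + params$oi / kin$Ko)),
    electron_transport = list(f0 = J / 4, gamma = 2 * kin$Gamma_star),
    Gamma_star = kin$Gamma_star, Rd = Rd,
    Kc = kin$Kc, Ko = kin$Ko), class = "photo_at_T")
}

#' Net assimilation at a given intercellular CO2
#'
#' The generic single-branch model
#' `An = f0 * (ci - Gamma_star) / (ci + gamma) - Rd`.
#'
#' @param ci Intercellular CO2 mole fraction (mol mol^-1, > 0).
#' @param f0,gamma Branch coefficients (see [photo_at_T()]).
#' @param Gamma_star CO2 compensation point (mol mol^-1).
#' @param Rd Dark respiration (mol m^-2 s^-1).
#' @return Net assimilation (mol m^-2 s^-1).
#' @export
an_of_ci <- function(ci, f0, gamma, Gamma_star, Rd) {
  if (any(ci <= 0, na.rm = TRUE)) stop("ci must be positive")
  f0 * (ci - Gamma_star) / (ci + gamma) - Rd
}

#' One-point estimate of Vcmax from a single light-saturated observation
#'
#' `Vcmax = An / ((ci - Gamma_star) / (ci + Kc * (1 + oi / Ko)) - 0.015)`
#' with kinetics at the observation temperature, assuming
#' `Rd = 0.015 * Vcmax`.
#'
#' @param An_obs Observed net assimilation (mol m^-2 s^-1).
#' @param ci_obs Observed intercellular CO2 (mol mol^-1).
#' @param T_L Leaf temperature (K).
#' @param params A [photo_params()] object supplying kinetic constants.
#' @param flag_above Estimates above this value (mol m^-2 s^-1) are
#'   flagged as degenerate (`ci` barely above the compensation point).
#' @return Vcmax at `T_L` (mol m^-2 s^-1), with attribute `flagged`.
#' @export
one_point_vcmax <- function(An_obs, ci_obs, T_L,
                            params = photo_params(Vcmax25 = 50e-6),
                            flag_above = 500e-6) {
  kin <- kinetics_at_T(T_L, params)
  if (any(ci_obs <= kin$Gamma_star)) {
    stop("one-point estimation failure: ci at or below the compensation point")
  }
  denom <- (ci_obs - kin$Gamma_star) /
    (ci_obs + kin$Kc * (1 + params$oi / kin$Ko)) - 0.015
  if (any(denom <= 0)) {
    stop("one-point estimation failure: non-positive denominator")
  }
  v <- An_obs / denom
  structure(v, flagged = v > flag_above)
}
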