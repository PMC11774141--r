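#' Latent heat of vaporization of water
#'
#' Standard linear approximation `2.501e6 - 2370 * (T - 273.15)` J kg^-1.
#'
#' @param T_LK Temperature (K), within \[250, 340\].
#' @return Latent heat (J kg^-1).
#' @export
latent_heat <- function(T_LK) {
  if (any(T_LK < 250 | T_LK > 340)) {
    stop("T_LK outside the supported range [250, 340] K")
  }
  2.501e6 - 2370 * (T_LK - 273.15)
}

#' Rate of change of the mesophyll osmotic potential
#'
#' The mechanistic non-steady-state model behind the marginal carbon
#' cost of water.  Net assimilation `An` adds osmolytes to the symplast
#' at rate `An / alpha` (van't Hoff: lowers `pi_L`); transpiration `E`
#' removes water from the leaf store, concentrating the symplast (the
#' apoplastic fraction responds to `pi_L` through its Weibull relation,
#' which feeds back on the rate); and the evaporative heat sink cools
#' the leaf, scaling `pi_L` toward zero because `pi_L` is proportional
#' to absolute temperature.
#'
#' The rate follows from differentiating the van't Hoff constraint
#' `pi_L * (RWC_LT - af(pi_L)) * V_sat = -varpi * R * T * n_s`
#' along the stock dynamics, with
#' `dRWC/dt = -E * mw / (rho_w * V_sat)` and
#' `dT/dt = -Lambda_E * mw * E / C_heat`.
#'
#' @param An Net CO2 assimilation (mol m^-2 s^-1).
#' @param E Transpiration (mol m^-2 s^-1).
#' @param state A `leaf_state` (see [state_from_psi()]).
#' @param params A [leaf_pv_params()] object.
#' @param lma Leaf dry mass per area (kg m^-2); needed only to convert
#'   per-area fluxes to per-leaf stocks and cancels from the cost ratio.
#' @return d pi_L / dt (MPa s^-1).
#' @export
pi_dot <- function(An, E, state, params, lma = 0.1) {
  cn <- params$constants
  T_LK <- state$T_LK
  pi_L <- state$pi_L
  RWC <- state$RWC_LT
  af <- state$a_f
  V_sat <- params$SWC_L * lma / cn$rho_w              # m^3 water m^-2 leaf
  V_s <- (RWC - af) * V_sat                           # symplast water
  C_heat <- (params$SWC_L * RWC * cn$cw + params$c_DM) * lma  # J K^-1 m^-2

  dRWC_dt <- -E * cn$mw / (cn$rho_w * V_sat)
  dT_dt <- -latent_heat(T_LK) * cn$mw * E / C_heat
  dn_dt <- An / params$alpha                          # mol osmolyte m^-2 s^-1

  # d af / d pi_L, from the Weibull response
  r_beta <- (pi_L / params$pi_L_star)^params$beta
  daf_dpi <- -af * params$beta * r_beta / pi_L
  denom <- V_sat * (RWC - af - pi_L * daf_dpi)

  num <- pi_L * V_sat * dRWC_dt +
    cn$varpi * cn$R * T_LK * dn_dt -
    pi_L * (RWC - af) * V_sat * dT_dt / T_LK
  -num / denom
}

#' Marginal carbon cost of water by finite differences
#'
#' The defining ratio `chi_w = -(d pi_dot / dE) / (d pi_dot / dAn)`,
#' evaluated by central finite differences of [pi_dot()] around the
#' given flux point.  `pi_dot` is linear in both fluxes, so the result
#' is independent of the linearization point and of the step size; this
#' function is the package's normative definition of the cost, against
#' which the closed form is verified.
#'
#' @inheritParams pi_dot
#' @param An0,E0 Flux point around which to differentiate.
#' @param rel_step Relative step on the characteristic flux scales
#'   (1e-5 mol m^-2 s^-1 for `An`, 1e-3 for `E`).
#' @return Marginal carbon cost of water (mol CO2 per mol H2O).
#' @export
chi_w_numeric <- function(state, params, lma = 0.1, An0 = 0, E0 = 0,
                          rel_step = 1e-8) {
  hA <- rel_step * 1e-5
  hE <- rel_step * 1e-3
  dAn <- (pi_dot(An0 + hA, E0, state, params, lma) -
            pi_dot(An0 - hA, E0, state, params, lma)) / (2 * hA)
  dE <- (pi_dot(An0, E0 + hE, state, params, lma) -
           pi_dot(An0, E0 - hE, state, params, lma)) / (2 * hE)
  if (any(dAn >= 0) || any(abs(dAn) < 1e-300)) {
    stop("degenerate leaf state: d pi_dot / d An must be negative")
  }
  -dE / dAn
}

#' Unitless apoplast-feedback shorthand
#'
#' The diagnostic combination
#' `Delta = 1 - (eps_L0 / (eps_L0 - pi_L0)) * beta * (af_0 / (1 - af_0))
#'  * (pi_L / pi_L_star)^beta`,
#' summarizing how strongly the Weibull apoplast response and the
#' elastic modulus shape the leaf's water bookkeeping at the current
#' osmotic potential.  `Delta = 1` in the rigid-apoplast limit
#' (`af_0 -> 0`) and declines as the symplast concentrates.  Note that
#' this combination cancels from the marginal cost itself when the cost
#' is evaluated at a fixed leaf state (see [chi_w_closed()]); it is kept
#' as a standalone diagnostic of the apoplast feedback strength.
#'
#' @inheritParams pi_dot
#' @return Unitless Delta.
#' @export
delta_term <- function(state, params) {
  pi_L0 <- pi_L0_at_T(params$pi_L0_25, state$T_LK)
  af0 <- af0_at_T(params, state$T_LK)
  r_beta <- (state$pi_L / params$pi_L_star)^params$beta
  1 - (params$eps_L0 / (params$eps_L0 - pi_L0)) * params$beta *
    (af0 / (1 - af0)) * r_beta
}

#' Marginal carbon cost of water, closed form
#'
#' Closed-form solution of the cost ratio derived from the same
#' non-steady-state leaf physics as [pi_dot()]:
#'
#' `chi_w = pi_L0(T) * (1 - af_0) * alpha * mw / (varpi * R * T * rho_w)
#'   * [ 1 / (RWC_LT - af)
#'       - SWC_L * Lambda_E / ((SWC_L * RWC_LT * cw + c_DM) * T) ]`
#'
#' The first bracket term is the symplast-concentration effect of
#' transpiration and the second its evaporative-cooling effect; with
#' `pi_L0 < 0` the cost is positive whenever cooling dominates, rises as
#' the leaf dehydrates toward the wilting point for trait sets passing
#' the wilting-closure filter, falls with leaf temperature (the
#' `Lambda_E / T` term), and grows as the osmotic potential at full
#' hydration becomes more negative (the carbon-use feedback).  The
#' apoplast-feedback factor common to both partial derivatives of
#' `pi_dot` cancels in the ratio, which is why [delta_term()] does not
#' appear.  Agreement with [chi_w_numeric()] to near machine precision
#' is enforced by the test suite.
#'
#' @inheritParams pi_dot
#' @param strict If `TRUE` (default), a negative result raises an error:
#'   for physiological states a negative cost signals a sign-convention
#'   bug rather than a data problem.  Set to `FALSE` to explore extreme
#'   corners of trait space where the concentration benefit genuinely
#'   exceeds the cooling cost.
#' @return Marginal carbon cost of water (mol CO2 per mol H2O).
#' @export
chi_w_closed <- function(state, params, strict = TRUE) {
  cn <- params$constants
  T_LK <- state$T_LK
  pi_L0 <- pi_L0_at_T(params$pi_L0_25, T_LK)
  af0 <- af0_at_T(params, T_LK)
  conc <- 1 / (state$RWC_LT - state$a_f)
  cool <- params$SWC_L * latent_heat(T_LK) /
    ((params$SWC_L * state$RWC_LT * cn$cw + params$c_DM) * T_LK)
  chi <- pi_L0 * (1 - af0) * params$alpha * cn$mw /
    (cn$varpi * cn$R * T_LK * cn$rho_w) * (conc - cool)
  if (strict && any(chi < 0)) {
    stop("closed-form inconsistency: chi_w came out negative for a ",
         "physiological state; check sign conventions")
  }
  chi
}

# Vectorized closed form used on the calibration hot path: takes raw
# state vectors instead of a leaf_state object.
chi_w_closed_vec <- function(pi_L, RWC, af, T_LK, params) {
  cn <- params$constants
  pi_L0 <- pi_L0_at_T(params$pi_L0_25, T_LK)
  af0 <- af0_at_T(params, T_LK)
  conc <- 1 / (RWC - af)
  cool <- params$SWC_L * latent_heat(T_LK) /
    ((params$SWC_L * RWC * cn$cw + params$c_DM) * T_LK)
  pi_L0 * (1 - af0) * params$alpha * cn$mw /
    (cn$varpi * cn$R * T_LK * cn$rho_w) * (conc - cool)
}
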