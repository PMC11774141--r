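#' Physical constants used throughout the package
#'
#' Bundles the handful of physical constants that the leaf water, carbon
#' and energy bookkeeping needs.  All values are SI unless noted; water
#' potentials elsewhere in the package are expressed in MPa, hence the
#' Pa-to-MPa conversion factor `varpi`.
#'
#' @param mw Molar mass of water (kg mol^-1).
#' @param rho_w Density of liquid water (kg m^-3).
#' @param cw Specific heat of liquid water (J K^-1 kg^-1).
#' @param R Universal gas constant (J mol^-1 K^-1).
#' @param varpi Pa to MPa conversion factor (MPa Pa^-1).
#'
#' @return An object of class `physical_constants`.
#' @export
physical_constants <- function(mw = 0.018015, rho_w = 1000, cw = 4184,
                               R = 8.314, varpi = 1e-6) {
  vals <- c(mw = mw, rho_w = rho_w, cw = cw, R = R, varpi = varpi)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all physical constants must be finite and strictly positive")
  }
  structure(as.list(vals), class = "physical_constants")
}

#' Leaf pressure-volume parameters
#'
#' The trait set governing leaf pressure-volume behaviour and, through
#' it, the marginal carbon cost of water: the Weibull apoplastic-fraction
#' response (`af_max`, `pi_L_star`, `beta`), the bulk elastic modulus at
#' full hydration (`eps_L0`), the saturated water content (`SWC_L`), the
#' carbon-atom count of the first photosynthetic osmolyte (`alpha`), the
#' osmotic potential at full hydration at 25 degC (`pi_L0_25`,
#' treatment-specific), and the dry-matter specific heat (`c_DM`).
#'
#' @param af_max Maximum apoplastic fraction (m^3 m^-3), in (0, 1).
#' @param pi_L_star Weibull scale for the apoplastic fraction (MPa, < 0).
#' @param beta Weibull shape (unitless, > 0).
#' @param eps_L0 Bulk elastic modulus at full hydration (MPa, > 0).
#' @param SWC_L Saturated water content (kg water per kg dry mass, > 0).
#' @param alpha Carbon atoms per first-formed photosynthetic osmolyte
#'   (mol mol^-1, > 0); e.g. 3 for triose phosphate, 12 for sucrose.
#' @param pi_L0_25 Osmotic potential at full hydration at 25 degC
#'   (MPa, < 0).
#' @param c_DM Dry-matter specific heat (J K^-1 kg^-1).
#' @param constants A [physical_constants()] object.
#'
#' @return An object of class `leaf_pv_params`.
#' @export
leaf_pv_params <- function(af_max, pi_L_star, beta, eps_L0, SWC_L, alpha,
                           pi_L0_25, c_DM = 1300,
                           constants = physical_constants()) {
  stopifnot(is.numeric(af_max), is.numeric(pi_L_star), is.numeric(beta),
            is.numeric(eps_L0), is.numeric(SWC_L), is.numeric(alpha),
            is.numeric(pi_L0_25), is.numeric(c_DM))
  if (!(af_max > 0 && af_max < 1)) stop("af_max must lie in (0, 1)")
  if (!(pi_L_star < 0)) stop("pi_L_star must be negative (MPa)")
  if (!(beta > 0)) stop("beta must be positive")
  if (!(eps_L0 > 0)) stop("eps_L0 must be positive (MPa)")
  if (!(SWC_L > 0)) stop("SWC_L must be positive")
  if (!(alpha > 0)) stop("alpha must be positive")
  if (!(pi_L0_25 < 0)) stop("pi_L0_25 must be negative (MPa)")
  if (!(c_DM > 0)) stop("c_DM must be positive")
  p <- structure(list(af_max = af_max, pi_L_star = pi_L_star, beta = beta,
                      eps_L0 = eps_L0, SWC_L = SWC_L, alpha = alpha,
                      pi_L0_25 = pi_L0_25, c_DM = c_DM,
                      constants = constants),
                 class = "leaf_pv_params")
  af0 <- apoplastic_fraction(pi_L0_25, p)
  if (!(af0 > 0 && af0 < af_max && af0 < 1 - 1e-9)) {
    stop("derived apoplastic fraction at full hydration must satisfy ",
         "0 < af_0 < af_max < 1")
  }
  p
}

#' @export
print.leaf_pv_params <- function(x, ...) {
  cat("Leaf pressure-volume parameters\n")
  cat(sprintf("  af_max   %.4g    pi_L_star %.4g MPa   beta %.4g\n",
              x$af_max, x$pi_L_star, x$beta))
  cat(sprintf("  eps_L0   %.4g MPa  SWC_L   %.4g      alpha %.4g\n",
              x$eps_L0, x$SWC_L, x$alpha))
  cat(sprintf("  pi_L0_25 %.4g MPa  c_DM    %.4g J/K/kg\n",
              x$pi_L0_25, x$c_DM))
  invisible(x)
}

#' Photosynthesis parameters
#'
#' Farquhar-type parameter set: capacities at 25 degC, temperature
#' response constants (Arrhenius activation energies; optional peaked
#' deactivation terms for the capacities), the light response of electron
#' transport, and a sigmoidal water-stress downregulation of the
#' capacities.
#'
#' Michaelis constants and the CO2 compensation point default to
#' Bernacchi-style 25 degC references.  Dark respiration defaults to
#' 1.5% of `Vcmax25`, consistent with the one-point capacity estimator.
#'
#' @param Vcmax25 Maximum carboxylation rate at 25 degC (mol m^-2 s^-1).
#' @param Jmax25 Maximum electron transport rate at 25 degC
#'   (mol m^-2 s^-1); defaults to `1.8 * Vcmax25`.
#' @param Rd25 Dark respiration at 25 degC (mol m^-2 s^-1).
#' @param quantum_yield Apparent quantum yield of electron transport
#'   (mol electrons per mol incident photons).
#' @param curvature Curvature of the non-rectangular light-response
#'   hyperbola, in (0, 1).
#' @param sf Water-stress sensitivity (MPa^-1) of the sigmoidal
#'   downregulation of capacities.
#' @param psi_f Water potential (MPa) at the inflection of the
#'   water-stress response.
#' @param oi Intercellular O2 mole fraction (mol mol^-1).
#' @param Kc25,Ko25,Gamma_star25 Michaelis constants for carboxylation
#'   and oxygenation, and the photorespiratory CO2 compensation point,
#'   at 25 degC (mol mol^-1).
#' @param Ea_Vcmax,Ea_Jmax,Ea_Rd,Ea_Kc,Ea_Ko,Ea_Gamma_star Activation
#'   energies (J mol^-1).
#' @param Hd Deactivation energy of the peaked capacity response
#'   (J mol^-1).
#' @param dS_Vcmax,dS_Jmax Entropy terms of the peaked capacity response
#'   (J mol^-1 K^-1).
#'
#' @return An object of class `photo_params`.
#' @export
photo_params <- function(Vcmax25, Jmax25 = 1.8 * Vcmax25,
                         Rd25 = 0.015 * Vcmax25,
                         quantum_yield = 0.28, curvature = 0.9,
                         sf = 2.5, psi_f = -2.0, oi = 0.21,
                         Kc25 = 404.9e-6, Ko25 = 278.4e-3,
                         Gamma_star25 = 42.75e-6,
                         Ea_Vcmax = 65330, Ea_Jmax = 43540, Ea_Rd = 46390,
                         Ea_Kc = 79430, Ea_Ko = 36380,
                         Ea_Gamma_star = 37830,
                         Hd = 2e5, dS_Vcmax = 640, dS_Jmax = 647) {
  if (!(Vcmax25 > 0 && Jmax25 > 0 && Rd25 >= 0)) {
    stop("photosynthetic capacities must be positive")
  }
  if (!(curvature > 0 && curvature < 1)) stop("curvature must be in (0, 1)")
  structure(list(Vcmax25 = Vcmax25, Jmax25 = Jmax25, Rd25 = Rd25,
                 quantum_yield = quantum_yield, curvature = curvature,
                 sf = sf, psi_f = psi_f, oi = oi,
                 Kc25 = Kc25, Ko25 = Ko25, Gamma_star25 = Gamma_star25,
                 Ea_Vcmax = Ea_Vcmax, Ea_Jmax = Ea_Jmax, Ea_Rd = Ea_Rd,
                 Ea_Kc = Ea_Kc, Ea_Ko = Ea_Ko,
                 Ea_Gamma_star = Ea_Gamma_star,
                 Hd = Hd, dS_Vcmax = dS_Vcmax, dS_Jmax = dS_Jmax),
            class = "photo_params")
}

#' Soil-plant hydraulic parameters
#'
#' Lumped soil-to-leaf conductance declining exponentially with leaf
#' water potential, with a Q10-type temperature dependence.
#'
#' @param k_max Saturated soil-plant conductance per unit leaf area
#'   (mol m^-2 s^-1 MPa^-1).
#' @param d_k e-folding water potential of the conductance decline
#'   (MPa, > 0; entered as a positive magnitude).
#' @param Q10 Multiplicative rate change per 10 K (>= 1).
#' @param T_ref Reference temperature for the Q10 factor (K).
#'
#' @return An object of class `hydraulic_params`.
#' @export
hydraulic_params <- function(k_max, d_k, Q10 = 1.5, T_ref = 298.15) {
  if (!(k_max > 0 && d_k > 0 && Q10 >= 1 && T_ref > 0)) {
    stop("hydraulic parameters must be positive (Q10 >= 1)")
  }
  structure(list(k_max = k_max, d_k = d_k, Q10 = Q10, T_ref = T_ref),
            class = "hydraulic_params")
}

#' Leaf energy-balance parameters
#'
#' Minimalist steady-state leaf energy balance: isothermal net radiation
#' absorbed by the leaf, a linearized longwave feedback around air
#' temperature, two-sided sensible heat exchange through a fixed
#' boundary-layer conductance, and evaporative cooling.
#'
#' @param Q_abs Isothermal net radiation absorbed by the leaf (W m^-2),
#'   i.e. net radiation when the leaf is at air temperature.
#' @param emissivity Leaf thermal emissivity.
#' @param g_bH Boundary-layer conductance to heat (mol m^-2 s^-1),
#'   one-sided.
#' @param n_sides Number of exchanging leaf sides (1 or 2).
#'
#' @return An object of class `energy_balance_params`.
#' @export
energy_balance_params <- function(Q_abs = 300, emissivity = 0.97,
                                  g_bH = 1.5, n_sides = 2) {
  if (!(g_bH > 0)) stop("boundary-layer conductance must be positive")
  if (!(emissivity > 0 && emissivity <= 1)) stop("emissivity must be in (0,1]")
  structure(list(Q_abs = Q_abs, emissivity = emissivity, g_bH = g_bH,
                 n_sides = n_sides),
            class = "energy_balance_params")
}

#' Soil water-bucket parameters
#'
#' Campbell-type retention curve and a single-coefficient soil
#' evaporation model for the root-zone bucket.
#'
#' @param theta_sat Saturated volumetric water content (m^3 m^-3).
#' @param psi_e Air-entry water potential (MPa, < 0).
#' @param b_ret Retention-curve exponent (> 0).
#' @param Z_r Root-zone depth (m).
#' @param evap_coef Soil evaporation as a fraction of equilibrium
#'   evaporation at saturation.
#' @param theta_res Residual water content below which the bucket cannot
#'   be drawn down (m^3 m^-3).
#'
#' @return An object of class `soil_params`.
#' @export
soil_params <- function(theta_sat = 0.45, psi_e = -0.0015, b_ret = 5,
                        Z_r = 0.8, evap_coef = 0.12, theta_res = 0.02) {
  if (!(theta_sat > 0 && theta_sat < 1)) stop("theta_sat must be in (0, 1)")
  if (!(psi_e < 0)) stop("psi_e must be negative (MPa)")
  if (!(b_ret > 0)) stop("b_ret must be positive")
  if (!(Z_r > 0)) stop("Z_r must be positive")
  if (!(theta_res >= 0 && theta_res < theta_sat)) {
    stop("theta_res must lie in [0, theta_sat)")
  }
  structure(list(theta_sat = theta_sat, psi_e = psi_e, b_ret = b_ret,
                 Z_r = Z_r, evap_coef = evap_coef, theta_res = theta_res),
            class = "soil_params")
}

#' Atmospheric environment at the leaf
#'
#' @param ca Ambient CO2 mole fraction (mol mol^-1).
#' @param D_L Leaf-to-air vapour pressure deficit (kPa, > 0).
#' @param Patm Atmospheric pressure (kPa).
#' @param PPFD Photosynthetic photon flux density (mol m^-2 s^-1).
#' @param T_air Air temperature (K).
#' @param RH Relative humidity (fraction).
#'
#' @return An object of class `leaf_environment`.
#' @export
leaf_environment <- function(ca = 420e-6, D_L = 1.5, Patm = 101.325,
                             PPFD = 1.5e-3, T_air = 298.15, RH = 0.5) {
  if (!(D_L > 0)) stop("D_L must be positive (kPa)")
  if (!(Patm >= 50 && Patm <= 110)) stop("Patm must lie in [50, 110] kPa")
  if (!(ca > 0)) stop("ca must be positive")
  structure(list(ca = ca, D_L = D_L, Patm = Patm, PPFD = PPFD,
                 T_air = T_air, RH = RH),
            class = "leaf_environment")
}
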