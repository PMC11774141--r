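#' USO (Medlyn) stomatal conductance
#'
#' Solves the coupled system
#' `gw = g0 + 1.6 * (1 + g1 / sqrt(D_L)) * An / ca`
#' with `An` from the diffusion-demand coupling, by damped fixed-point
#' iteration to 1e-10.
#'
#' @param env A [leaf_environment()].
#' @param pat A [photo_at_T()] object.
#' @param g1 USO slope parameter (kPa^0.5, > 0).
#' @param g0 Conductance offset (mol m^-2 s^-1).
#' @param An_imposed Optional fixed assimilation rate; when supplied the
#'   coupling is bypassed (useful for decoupled checks).
#' @return A `gas_exchange` object.
#' @export
uso_gw <- function(env, pat, g1, g0 = 0, An_imposed = NULL) {
  if (any(g1 < 0)) stop("g1 must be non-negative")
  fac <- 1.6 * (1 + g1 / sqrt(env$D_L)) / env$ca
  if (!is.null(An_imposed)) {
    gw <- g0 + fac * An_imposed
    return(structure(list(gw = gw, An = An_imposed,
                          E = gw * env$D_L / env$Patm, ci = NA_real_,
                          x = NA_real_, limitation = "imposed",
                          lambda_used = NA_real_, closed = FALSE),
                     class = "gas_exchange"))
  }
  an_at <- function(gw) {
    cc <- ci_given_gw(gw, env$ca, pat$carboxylation$f0,
                      pat$carboxylation$gamma, pat$Gamma_star, pat$Rd)
    ce <- ci_given_gw(gw, env$ca, pat$electron_transport$f0,
                      pat$electron_transport$gamma, pat$Gamma_star, pat$Rd)
    Ac <- an_of_ci(cc, pat$carboxylation$f0, pat$carboxylation$gamma,
                   pat$Gamma_star, pat$Rd)
    Ae <- an_of_ci(ce, pat$electron_transport$f0,
                   pat$electron_transport$gamma, pat$Gamma_star, pat$Rd)
    list(An = pmin(Ac, Ae), ci = ifelse(Ac <= Ae, cc, ce),
         lim = ifelse(Ac <= Ae, "carboxylation", "electron_transport"))
  }
  gw <- pmax(rep_len(0.1, max(length(fac), 1L)), g0 + 1e-4)
  for (i in seq_len(200L)) {
    a <- an_at(gw)
    gw_new <- pmax(g0 + fac * pmax(a$An, 0), pmax(g0, 1e-6))
    dg <- gw_new - gw
    gw <- gw + 0.6 * dg
    if (max(abs(dg)) < 1e-10) break
  }
  if (max(abs(dg)) >= 1e-10) stop("USO fixed point failed to converge")
  a <- an_at(gw)
  structure(list(gw = gw, An = a$An, E = gw * env$D_L / env$Patm,
                 ci = a$ci, x = (a$ci - pat$Gamma_star) /
                   (env$ca - pat$Gamma_star),
                 limitation = a$lim, lambda_used = NA_real_,
                 closed = FALSE), class = "gas_exchange")
}

#' Fit the USO slope parameter to observed conductances
#'
#' Scalar minimization of the root-mean-square error between observed
#' and USO-predicted stomatal conductance over `g1` in (0.1, 20\].
#'
#' @param data Data frame with columns `gw_obs`, `D_L`, `ca`, `PPFD`,
#'   `Patm`, `T_leaf` and optionally `An_obs` (used preferentially, to
#'   isolate the conductance model from the photosynthesis model).
#' @param photo A [photo_params()] object, used when `An_obs` is absent.
#' @param g0 Conductance offset (mol m^-2 s^-1).
#' @return Fitted `g1` (kPa^0.5), with attribute `rmse`.
#' @export
fit_g1 <- function(data, photo = NULL, g0 = 0) {
  if (nrow(data) < 10 || any(data$gw_obs <= 0)) {
    stop("need >= 10 observations with positive gw")
  }
  use_obs_an <- "An_obs" %in% names(data) && !anyNA(data$An_obs)
  pred <- function(g1) {
    if (use_obs_an) {
      1.6 * (1 + g1 / sqrt(data$D_L)) * data$An_obs / data$ca + g0
    } else {
      vapply(seq_len(nrow(data)), function(i) {
        env <- leaf_environment(ca = data$ca[i], D_L = data$D_L[i],
                                Patm = data$Patm[i], PPFD = data$PPFD[i],
                                T_air = data$T_leaf[i])
        pat <- photo_at_T(photo, data$T_leaf[i], data$PPFD[i])
        uso_gw(env, pat, g1, g0 = g0)$gw
      }, 0)
    }
  }
  obj <- function(g1) sqrt(mean((data$gw_obs - pred(g1))^2))
  opt <- stats::optimize(obj, interval = c(0.1, 20), tol = 1e-6)
  rng <- obj(0.1) - opt$objective
  if (is.finite(rng) && rng < 1e-10) {
    warning("flat RMSE objective: g1 is weakly identified")
  }
  structure(opt$minimum, rmse = opt$objective)
}

#' Constant marginal-cost (Cowan-Farquhar) stomatal conductance
#'
#' The classic optimality scheme: the marginal water price is a fixed
#' constant, so only the indirect temperature and light responses of the
#' photosynthetic parameters move the stomata.
#'
#' @param lambda_const Fixed marginal cost (mol CO2 per mol H2O, > 0).
#' @inheritParams gw_from_lambda_closed
#' @return A `gas_exchange` object.
#' @export
cowan_farquhar_gw <- function(lambda_const, env, pat, g0_min = 0.005,
                              gw_cap = 5) {
  if (any(lambda_const <= 0)) stop("lambda_const must be positive")
  gw_from_lambda_closed(lambda_const, env, pat, g0_min = g0_min,
                        gw_cap = gw_cap)
}

# Invert the subcritical branch of the supply curve: the psi_L in
# [psi_crit, psi_s] at which supply equals E.  Newton on
# u = (psi_s - psi_L) / d_k solving u * exp(-u) = c, u in [0, 1].
supply_inverse_subcritical <- function(E, psi_s, T_L, hyd) {
  kf <- hyd$k_max * exp(psi_s / hyd$d_k) *
    hyd$Q10^((T_L - hyd$T_ref) / 10) * hyd$d_k
  cc <- pmin(E / kf, exp(-1))
  u <- pmin(pmax(cc, 1e-12), 0.99)
  for (i in seq_len(50L)) {
    f <- u * exp(-u) - cc
    fp <- exp(-u) * (1 - u)
    step <- f / pmax(fp, 1e-300)
    u <- pmin(pmax(u - step, 0), 1)
    if (max(abs(step)) < 1e-14) break
  }
  psi_s - hyd$d_k * u
}

#' Sperry-type Gain-Risk stomatal conductance
#'
#' Instantaneous optimization of normalized carbon gain minus
#' normalized hydraulic risk:
#' `gw* = argmax  An(gw) / An(E_crit) - (k(psi_s) - k(psi_L(gw))) / k(psi_s)`
#' over `gw` in `[g0_min, gw(E_crit)]`, with `psi_L(gw)` from inversion
#' of the subcritical supply branch.  Golden-section search (via
#' `stats::optimize`) at 1e-8 tolerance; the bounded search domain means
#' this scheme never returns supercritical water potentials.
#'
#' @param psi_s Soil water potential (MPa, <= 0).
#' @param env A [leaf_environment()].
#' @param pat A [photo_at_T()] object.
#' @param hyd A [hydraulic_params()] object.
#' @param T_L Leaf temperature (K) for the hydraulic temperature factor.
#' @param g0_min Conductance floor (mol m^-2 s^-1).
#' @return A `gas_exchange` object with attributes `psi_L` and `PLC`.
#' @export
gain_risk_gw <- function(psi_s, env, pat, hyd, T_L = env$T_air,
                         g0_min = 0.005) {
  crit <- critical_point(psi_s, T_L, hyd)
  gw_crit <- crit$E_crit * env$Patm / env$D_L
  if (gw_crit <= g0_min) {
    psi_L <- supply_inverse_subcritical(g0_min * env$D_L / env$Patm,
                                        psi_s, T_L, hyd)
    return(gr_exchange(g0_min, psi_L, env, pat, hyd, T_L, closed = TRUE))
  }
  k_soil <- conductance(psi_s, T_L, hyd)
  an_at <- function(gw) {
    cc <- ci_given_gw(gw, env$ca, pat$carboxylation$f0,
                      pat$carboxylation$gamma, pat$Gamma_star, pat$Rd)
    ce <- ci_given_gw(gw, env$ca, pat$electron_transport$f0,
                      pat$electron_transport$gamma, pat$Gamma_star, pat$Rd)
    pmin(an_of_ci(cc, pat$carboxylation$f0, pat$carboxylation$gamma,
                  pat$Gamma_star, pat$Rd),
         an_of_ci(ce, pat$electron_transport$f0,
                  pat$electron_transport$gamma, pat$Gamma_star, pat$Rd))
  }
  An_max <- max(an_at(gw_crit), 1e-12)
  obj <- function(gw) {
    E <- gw * env$D_L / env$Patm
    psi_L <- supply_inverse_subcritical(E, psi_s, T_L, hyd)
    gain <- an_at(gw) / An_max
    risk <- (k_soil - conductance(psi_L, T_L, hyd)) / k_soil
    gain - risk
  }
  opt <- stats::optimize(obj, interval = c(g0_min, gw_crit),
                         maximum = TRUE, tol = 1e-8)
  gw <- opt$maximum
  psi_L <- supply_inverse_subcritical(gw * env$D_L / env$Patm, psi_s,
                                      T_L, hyd)
  gr_exchange(gw, psi_L, env, pat, hyd, T_L, closed = FALSE)
}

gr_exchange <- function(gw, psi_L, env, pat, hyd, T_L, closed) {
  cc <- ci_given_gw(gw, env$ca, pat$carboxylation$f0,
                    pat$carboxylation$gamma, pat$Gamma_star, pat$Rd)
  ce <- ci_given_gw(gw, env$ca, pat$electron_transport$f0,
                    pat$electron_transport$gamma, pat$Gamma_star, pat$Rd)
  Ac <- an_of_ci(cc, pat$carboxylation$f0, pat$carboxylation$gamma,
                 pat$Gamma_star, pat$Rd)
  Ae <- an_of_ci(ce, pat$electron_transport$f0,
                 pat$electron_transport$gamma, pat$Gamma_star, pat$Rd)
  use_c <- Ac <= Ae
  structure(list(gw = gw, An = ifelse(use_c, Ac, Ae),
                 E = gw * env$D_L / env$Patm,
                 ci = ifelse(use_c, cc, ce),
                 x = (ifelse(use_c, cc, ce) - pat$Gamma_star) /
                   (env$ca - pat$Gamma_star),
                 limitation = ifelse(use_c, "carboxylation",
                                     "electron_transport"),
                 lambda_used = NA_real_, closed = closed),
            class = "gas_exchange", psi_L = psi_L,
            PLC = plc(psi_L, hyd))
}

#' Registry of stomatal schemes
#'
#' Names the stomatal schemes available to the simulators and the CLI.
#'
#' @return Character vector of scheme names.
#' @export
stomatal_schemes <- function() c("chi_w", "uso", "cowan", "gainrisk")
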