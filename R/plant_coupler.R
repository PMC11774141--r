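#' Soil-to-leaf hydraulic conductance
#'
#' Lumped conductance evaluated at the leaf-end water potential,
#' declining exponentially with `psi_L` and scaled by a Q10 temperature
#' factor: `k = k_max * exp(psi_L / d_k) * Q10^((T_L - T_ref) / 10)`.
#'
#' @param psi_L Leaf water potential (MPa, <= 0).
#' @param T_L Leaf temperature (K).
#' @param hyd A [hydraulic_params()] object.
#' @return Conductance (mol m^-2 s^-1 MPa^-1).
#' @export
conductance <- function(psi_L, T_L, hyd) {
  if (any(psi_L > 1e-12)) stop("psi_L must be <= 0")
  hyd$k_max * exp(psi_L / hyd$d_k) * hyd$Q10^((T_L - hyd$T_ref) / 10)
}

#' Hydraulic supply of transpiration
#'
#' Darcy-type supply `E = k(psi_L, T_L) * (psi_s - psi_L)`: zero when
#' the leaf equilibrates with the soil, rising to a maximum at the
#' critical water potential and collapsing as the exponential
#' conductance loss takes over.
#'
#' @param psi_s Soil water potential (MPa, <= 0).
#' @inheritParams conductance
#' @return Sustainable transpiration (mol m^-2 s^-1).
#' @export
supply <- function(psi_s, psi_L, T_L, hyd) {
  if (any(psi_L > psi_s + 1e-12)) {
    stop("psi_L must not exceed psi_s (water flows down-gradient)")
  }
  conductance(psi_L, T_L, hyd) * (psi_s - psi_L)
}

#' Critical point of the hydraulic supply curve
#'
#' The supply maximum has the closed form `psi_crit = psi_s - d_k`,
#' `E_crit = k(psi_crit, T_L) * d_k`.
#'
#' @inheritParams supply
#' @return List with `psi_crit` and `E_crit`.
#' @export
critical_point <- function(psi_s, T_L, hyd) {
  if (any(psi_s > 1e-12)) stop("psi_s must be <= 0")
  psi_crit <- psi_s - hyd$d_k
  list(psi_crit = psi_crit,
       E_crit = conductance(psi_crit, T_L, hyd) * hyd$d_k)
}

#' Percent loss of soil-plant conductance
#'
#' `PLC = 100 * (1 - exp(psi_L / d_k))`, referenced to the unstressed
#' conductance at `psi_L = 0`; the temperature factor is deliberately
#' excluded so that cooling does not register as conductance loss.
#'
#' @inheritParams conductance
#' @param hyd A [hydraulic_params()] object.
#' @return PLC in \[0, 100).
#' @export
plc <- function(psi_L, hyd) {
  if (any(psi_L > 1e-12)) stop("psi_L must be <= 0")
  100 * (1 - exp(psi_L / hyd$d_k))
}

STEFAN_BOLTZMANN <- 5.670374419e-8
CP_MOLAR_AIR <- 29.2  # J mol^-1 K^-1

# Linearized heat-loss coefficient (W m^-2 K^-1): two-sided sensible
# exchange plus longwave feedback linearized around air temperature.
heat_loss_coef <- function(env, eb) {
  eb$n_sides * (CP_MOLAR_AIR * eb$g_bH +
                  4 * eb$emissivity * STEFAN_BOLTZMANN * env$T_air^3)
}

#' Leaf energy-balance residual
#'
#' `residual = Q_abs - h * (T_L - T_air) - Lambda_E(T_L) * mw * E`
#' (W m^-2), with `h` the linearized sensible-plus-longwave loss
#' coefficient.  The residual is strictly decreasing in `T_L`, so the
#' balance has a unique root.
#'
#' @param T_L Leaf temperature (K).
#' @param E Transpiration (mol m^-2 s^-1).
#' @param env A [leaf_environment()].
#' @param eb An [energy_balance_params()] object.
#' @param mw Molar mass of water (kg mol^-1).
#' @return Energy imbalance (W m^-2).
#' @export
leaf_energy_balance <- function(T_L, E, env, eb, mw = 0.018015) {
  if (any(T_L < 250 | T_L > 340)) stop("T_L outside [250, 340] K")
  eb$Q_abs - heat_loss_coef(env, eb) * (T_L - env$T_air) -
    latent_heat(T_L) * mw * E
}

#' Leaf temperature satisfying the energy balance
#'
#' With the linearized loss term and the linear latent-heat formula the
#' balance is linear in `T_L` and solves in closed form.
#'
#' @inheritParams leaf_energy_balance
#' @return Leaf temperature (K).
#' @export
solve_leaf_temperature <- function(E, env, eb, mw = 0.018015) {
  h <- heat_loss_coef(env, eb)
  a <- 2370 * mw * E
  T_L <- (eb$Q_abs + h * env$T_air - mw * E * 2.501e6 - 273.15 * a) / (h - a)
  pmin(pmax(T_L, 250), 340)
}

coupler_control <- function(damping = 0.5, tol_T = 1e-8, tol_psi = 1e-8,
                            maxit = 200L, g0_min = 0.005, gw_cap = 5,
                            lambda_floor = 1e-7, peaked = TRUE,
                            water_stress = TRUE, inner_maxit = 60L) {
  list(damping = damping, tol_T = tol_T, tol_psi = tol_psi, maxit = maxit,
       g0_min = g0_min, gw_cap = gw_cap, lambda_floor = lambda_floor,
       peaked = peaked, water_stress = water_stress,
       inner_maxit = inner_maxit)
}

# Evaporative demand at prescribed leaf water potentials (vectorized
# over psi_L).  Damped fixed-point on leaf temperature: leaf state ->
# marginal cost -> gw -> transpiration -> energy-balance temperature.
demand_at_psi <- function(psi_L, env, photo, pv, eb, ctl, T_init = NULL) {
  n <- length(psi_L)
  e_air <- env$RH * esat_kpa(env$T_air)
  T_L <- rep_len(T_init %||% env$T_air, n)
  env_loc <- env
  # one full update of the leaf-temperature map at prescribed T_L
  one_update <- function(T_L) {
    pi_L <- pi_from_psi(psi_L, T_L, pv, extend = TRUE)
    af <- apoplastic_fraction(pi_L, pv)
    RWC <- rwc_from_pi(pi_L, T_L, pv)
    chi <- chi_w_closed_vec(pi_L, RWC, af, T_L, pv)
    # kinetics are evaluated inside their valid temperature range
    pat <- photo_at_T(photo, pmin(pmax(T_L, 273.7), 332.7), env$PPFD,
                      psi_L = if (ctl$water_stress) psi_L else NULL,
                      peaked = ctl$peaked)
    D_L <- vpd_leaf_kpa(T_L, e_air)
    env_loc$D_L <- D_L
    ge <- gw_from_lambda_closed(pmax(chi, ctl$lambda_floor), env_loc, pat,
                                g0_min = ctl$g0_min, gw_cap = ctl$gw_cap)
    E <- ge$gw * D_L / env$Patm
    list(T_new = solve_leaf_temperature(E, env, eb), ge = ge, E = E,
         D_L = D_L, chi = chi)
  }
  up <- NULL; dT <- Inf
  for (i in seq_len(ctl$inner_maxit)) {
    up <- one_update(T_L)
    dT <- up$T_new - T_L
    step <- ctl$damping * dT
    # geometric extrapolation of the damped fixed point once the step
    # ratio has settled (the damped map is linear near the solution)
    if (i > 2L) {
      r <- step / step_prev
      step <- ifelse(is.finite(r) & r > -0.5 & r < 0.95,
                     step / (1 - pmax(pmin(r, 0.95), -0.5)), step)
    }
    step_prev <- ctl$damping * dT
    T_L <- T_L + step
    if (max(abs(dT)) < ctl$tol_T) break
  }
  if (max(abs(dT)) >= ctl$tol_T) {
    # rare limit cycles of the damped map (e.g. dawn steps with the
    # VPD floor engaged): fall back to bisection on T - map(T), which
    # is monotone through the balance root
    T_L <- bisect_vec(function(T) T - one_update(T)$T_new,
                      rep_len(251, n), rep_len(339, n), iters = 50L)
    up <- one_update(T_L)
    dT <- up$T_new - T_L
  }
  list(E = up$E, T_L = T_L, D_L = up$D_L, ge = up$ge,
       chi = up$chi, converged = max(abs(dT)) < max(ctl$tol_T * 2, 1e-7))
}

# Supply minus demand at prescribed psi_L (vectorized).
supply_minus_demand <- function(psi_L, psi_s, env, photo, pv, hyd, eb, ctl,
                                T_init = NULL) {
  d <- demand_at_psi(psi_L, env, photo, pv, eb, ctl, T_init = T_init)
  supply(psi_s, pmin(psi_L, psi_s), d$T_L, hyd) - d$E
}

# Locate sign changes of G on a grid and refine all of them at once by
# vectorized bisection; return roots with their local slopes.
find_roots_on_grid <- function(psi_grid, G_grid, Gfun_vec) {
  s <- sign(G_grid)
  i_chg <- which(s[-length(s)] * s[-1] < 0 & !is.na(s[-length(s)]) &
                   !is.na(s[-1]))
  if (!length(i_chg)) return(list())
  lo <- pmin(psi_grid[i_chg], psi_grid[i_chg + 1])
  hi <- pmax(psi_grid[i_chg], psi_grid[i_chg + 1])
  flo <- ifelse(psi_grid[i_chg] <= psi_grid[i_chg + 1],
                G_grid[i_chg], G_grid[i_chg + 1])
  for (it in seq_len(30L)) {
    mid <- 0.5 * (lo + hi)
    fm <- Gfun_vec(mid)
    take_lo <- (flo * fm) <= 0
    hi <- ifelse(take_lo, mid, hi)
    lo <- ifelse(take_lo, lo, mid)
    flo <- ifelse(take_lo, flo, fm)
  }
  root <- 0.5 * (lo + hi)
  h <- 1e-4
  slope <- (Gfun_vec(root + h) - Gfun_vec(root - h)) / (2 * h)
  lapply(seq_along(root), function(i) list(psi = root[i],
                                           slope = slope[i]))
}

#' Coupled whole-plant operating point
#'
#' Solves the minimalist whole-plant model: the leaf state follows from
#' the leaf water potential through pressure-volume theory, the
#' marginal carbon cost of water sets the optimal stomatal conductance,
#' evaporative demand follows from the leaf-to-air VPD at the
#' energy-balance leaf temperature, and the leaf water potential must
#' reconcile that demand with the hydraulic supply from the soil.
#'
#' All demand-supply intersections over `(psi_s - 40 * d_k, psi_s]` are
#' classified; an intersection is dynamically stable when
#' supply-minus-demand decreases through zero as `psi_L` increases.  The
#' solver returns the stable subcritical root when one exists, otherwise
#' a stable supercritical root (`criticality = "supercritical-stable"`),
#' and otherwise the state at maximum supply with
#' `criticality = "desiccating"`.
#'
#' @param psi_s Soil water potential (MPa, <= 0).
#' @param env A [leaf_environment()] (its `D_L` field is ignored; the
#'   leaf-to-air VPD is computed at the solved leaf temperature).
#' @param photo,pv,hyd,eb Parameter objects.
#' @param control Solver settings from `coupler_control()`.
#' @param warm Optional list with `psi_L` and `T_L` from a previous
#'   solve, used to initialize the iteration.
#' @return An object of class `operating_point`: leaf state, gas
#'   exchange, `E_supply`, `psi_L`, `T_L`, `PLC`, `criticality`,
#'   `mismatch` (mol m^-2 s^-1) and `energy_residual` (W m^-2).
#' @export
solve_operating_point <- function(psi_s, env, photo, pv, hyd, eb,
                                  control = coupler_control(),
                                  warm = NULL) {
  ctl <- control
  crit <- critical_point(psi_s, env$T_air, hyd)
  # scanning uses a loosened inner tolerance; the returned point is
  # re-polished to the full tolerances afterwards
  ctl_scan <- ctl
  ctl_scan$tol_T <- 1e-5
  ctl_scan$inner_maxit <- 30L
  Gfun <- function(p) supply_minus_demand(p, psi_s, env, photo, pv, hyd,
                                          eb, ctl_scan,
                                          T_init = warm$T_L %||% NULL)
  psi_floor <- psi_s - 40 * hyd$d_k
  psi_L <- NULL; criticality <- NULL
  # warm-start fast path: secant from the previous step's root
  if (!is.null(warm$psi_L) && is.finite(warm$psi_L)) {
    p0 <- min(warm$psi_L, psi_s - 1e-6)
    p1 <- p0 - 0.02 * hyd$d_k
    g0 <- Gfun(p0); g1 <- Gfun(p1)
    ok <- FALSE; slope <- NA_real_
    for (i in seq_len(15L)) {
      if (!is.finite(g0) || !is.finite(g1) || g1 == g0) break
      slope <- (g1 - g0) / (p1 - p0)
      p2 <- p1 - g1 / slope
      if (!is.finite(p2) || p2 >= psi_s - 1e-9 || p2 <= psi_floor) break
      g2 <- Gfun(p2)
      p0 <- p1; g0 <- g1
      p1 <- p2; g1 <- g2
      if (abs(p1 - p0) < 1e-6 || abs(g1) < 1e-9) { ok <- TRUE; break }
    }
    if (ok) {
      if (abs(p1 - p0) > 1e-9) slope <- (g1 - g0) / (p1 - p0)
      if (is.finite(slope) && slope < 0) {
        if (p1 > crit$psi_crit) {
          psi_L <- p1; criticality <- "subcritical"
        } else {
          # supercritical root is valid only if no stable subcritical
          # root exists
          off <- c(1e-4, seq(0.1, 1, length.out = 8))
          ps <- psi_s - hyd$d_k * off
          Gs <- Gfun(ps)
          if (!any(diff(sign(Gs)) != 0, na.rm = TRUE)) {
            psi_L <- p1; criticality <- "supercritical-stable"
          }
        }
      }
    }
  }
  if (is.null(psi_L)) {
    # full scan: subcritical region first (a stable root there takes
    # priority), then the supercritical branch down to psi_s - 40 d_k.
    # When a scan finds no crossing but grazes zero (near-tangent
    # demand and supply), the neighbourhood of the grid maximum is
    # re-examined on a finer grid with a tighter inner tolerance.
    ctl_ref <- ctl_scan
    ctl_ref$tol_T <- 1e-7
    Gfun_ref <- function(p) supply_minus_demand(p, psi_s, env, photo, pv,
                                                hyd, eb, ctl_ref,
                                                T_init = warm$T_L %||%
                                                  NULL)
    scan_region <- function(psi_grid) {
      G <- Gfun(psi_grid)
      roots <- find_roots_on_grid(psi_grid, G, Gfun)
      if (!length(roots)) {
        j <- which.max(G)
        if (length(j) == 1 && is.finite(G[j]) && G[j] > -1e-4 &&
            G[j] < 0) {
          lo <- psi_grid[min(j + 1L, length(psi_grid))]
          hi <- psi_grid[max(j - 1L, 1L)]
          fine <- seq(hi, lo, length.out = 25)
          roots <- find_roots_on_grid(fine, Gfun_ref(fine), Gfun_ref)
        }
      }
      Filter(function(r) is.finite(r$slope) && r$slope < 0, roots)
    }
    off_sub <- c(1e-4, seq(0.05, 1, length.out = 14))
    stable <- scan_region(psi_s - hyd$d_k * off_sub)
    criticality <- "subcritical"
    if (length(stable) == 0) {
      off_sup <- c(seq(1, 4, length.out = 14), seq(4.5, 12, length.out = 8),
                   16, 24, 40)
      stable <- scan_region(psi_s - hyd$d_k * off_sup)
      criticality <- if (length(stable) > 0) "supercritical-stable"
                     else "desiccating"
    }
    psi_L <- if (length(stable) > 0) {
      stable[[which.max(vapply(stable, function(r) r$psi, 0))]]$psi
    } else {
      crit$psi_crit
    }
  }
  # polish the returned point with a tight inner loop
  ctl_tight <- ctl
  ctl_tight$inner_maxit <- ctl$maxit
  d <- demand_at_psi(psi_L, env, photo, pv, eb, ctl_tight,
                     T_init = warm$T_L %||% NULL)
  if (criticality != "desiccating") {
    # Newton polish on psi so the mismatch closes below tolerance
    for (i in seq_len(30L)) {
      G0 <- supply(psi_s, pmin(psi_L, psi_s), d$T_L, hyd) - d$E
      if (abs(G0) < 1e-11) break
      h <- 1e-6
      both <- supply_minus_demand(c(psi_L + h, psi_L - h), psi_s, env,
                                  photo, pv, hyd, eb, ctl_scan,
                                  T_init = d$T_L)
      slope <- (both[1] - both[2]) / (2 * h)
      if (!is.finite(slope) || slope == 0) break
      psi_L <- min(max(psi_L - G0 / slope, psi_floor),
                   min(psi_s, 0) - 1e-9)
      d <- demand_at_psi(psi_L, env, photo, pv, eb, ctl_tight,
                         T_init = d$T_L)
    }
  }
  state <- state_from_psi_any(psi_L, d$T_L, pv)
  E_sup <- supply(psi_s, pmin(psi_L, psi_s), d$T_L, hyd)
  structure(list(
    state = state, gas = d$ge, E_demand = d$E, E_supply = E_sup,
    psi_L = psi_L, T_L = d$T_L, D_L = d$D_L,
    PLC = plc(psi_L, hyd), criticality = criticality,
    psi_crit = crit$psi_crit, E_crit = crit$E_crit,
    mismatch = E_sup - d$E,
    energy_residual = leaf_energy_balance(d$T_L, d$E, env, eb),
    converged = isTRUE(d$converged),
    chi_w = d$chi), class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf(
    "Operating point [%s]: psi_L %.3f MPa  T_L %.2f K  gw %.4f  E %.3g  PLC %.1f%%\n",
    x$criticality, x$psi_L, x$T_L, x$gas$gw, x$E_demand, x$PLC))
  invisible(x)
}
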