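#' Soil water potential from the Campbell retention curve
#'
#' `psi_s = psi_e * (theta / theta_sat)^(-b_ret)`.
#'
#' @param theta Volumetric soil water content (m^3 m^-3, > 0).
#' @param soil A [soil_params()] object.
#' @return Soil water potential (MPa, <= psi_e).
#' @export
soil_retention <- function(theta, soil) {
  if (any(theta <= 0)) stop("theta must be positive")
  soil$psi_e * (pmin(theta, soil$theta_sat) / soil$theta_sat)^(-soil$b_ret)
}

#' Mean-canopy light from big-leaf extinction
#'
#' `PPFD * (1 - exp(-k_ext * LAI)) / (k_ext * LAI)`: the leaf-area-mean
#' photon flux under exponential extinction through the canopy.
#'
#' @param PPFD Above-canopy photon flux (mol m^-2 s^-1).
#' @param LAI Leaf area index (m^2 m^-2, >= 0).
#' @param k_ext Extinction coefficient.
#' @return Mean-canopy PPFD (mol m^-2 s^-1).
#' @export
light_scaling <- function(PPFD, LAI, k_ext = 0.5) {
  if (any(LAI < 0)) stop("LAI must be non-negative")
  f <- ifelse(LAI > 1e-9, (1 - exp(-k_ext * LAI)) / (k_ext * LAI), 1)
  PPFD * f
}

#' Per-leaf-area hydraulic conductance from ground-area conductance
#'
#' The soil-plant conductance per unit ground area is a property of the
#' root-soil system and is held fixed; the conductance per unit leaf
#' area is therefore inversely proportional to LAI.
#'
#' @param k_max_ground Saturated conductance per ground area
#'   (mol m^-2 s^-1 MPa^-1).
#' @param LAI Leaf area index (> 0).
#' @return Conductance per leaf area (mol m^-2 s^-1 MPa^-1).
#' @export
lai_conductance_scaling <- function(k_max_ground, LAI) {
  if (any(LAI <= 0)) stop("LAI must be positive; a zero-LAI canopy is absent")
  k_max_ground / LAI
}

#' Soil evaporation
#'
#' Single-coefficient model: a calibrated fraction of equilibrium
#' evaporation (Priestley-Taylor without the 1.26 multiplier, driven by
#' a shortwave estimate from PPFD), scaled linearly by relative soil
#' water content.  Zero in darkness and in dry soil.
#'
#' @param theta Soil water content (m^3 m^-3).
#' @param T_air Air temperature (K).
#' @param PPFD Photon flux (mol m^-2 s^-1).
#' @param soil A [soil_params()] object.
#' @return Evaporation as a water depth flux (m s^-1).
#' @export
soil_evaporation <- function(theta, T_air, PPFD, soil) {
  if (any(theta < 0)) stop("theta must be non-negative")
  sw <- PPFD * 1e6 / 2.3 * 2          # W m^-2 shortwave from PPFD
  rn <- 0.6 * sw
  Tc <- T_air - 273.15
  s <- esat_kpa(T_air) * 4098 / (Tc + 237.3)^2   # kPa K^-1
  gamma_psy <- 0.0665                            # kPa K^-1
  e_eq <- s / (s + gamma_psy) * rn / latent_heat(T_air)  # kg m^-2 s^-1
  soil$evap_coef * (e_eq / 1000) * (theta / soil$theta_sat)
}

# Night-time or canopy-absent leaf fluxes: cuticular conductance only.
night_fluxes <- function(psi_s, env, hyd, g0_min) {
  D <- vpd_leaf_kpa(env$T_air, env$RH * esat_kpa(env$T_air))
  E <- g0_min * D / env$Patm
  psi_L <- supply_inverse_subcritical(min(E, 0.99 * exp(-1) *
                                            conductance(psi_s, env$T_air, hyd) * hyd$d_k),
                                      psi_s, env$T_air, hyd)
  list(E = E, gw = g0_min, An = 0, T_L = env$T_air, psi_L = psi_L,
       criticality = "subcritical")
}

# Gain-Risk operating point with leaf-temperature coupling and
# water-stressed capacities at the realized leaf water potential.
solve_gainrisk_point <- function(psi_s, env, photo, pv, hyd, eb,
                                 control = coupler_control(),
                                 warm = NULL) {
  ctl <- control
  T_L <- warm$T_L %||% env$T_air
  psi_L <- min(warm$psi_L %||% psi_s, psi_s)
  e_air <- env$RH * esat_kpa(env$T_air)
  ge <- NULL
  dd_prev <- NULL
  for (i in seq_len(30L)) {
    env_loc <- env
    env_loc$D_L <- vpd_leaf_kpa(T_L, e_air)
    pat <- photo_at_T(photo, pmin(pmax(T_L, 273.7), 332.7), env$PPFD,
                      psi_L = if (ctl$water_stress) psi_L else NULL,
                      peaked = ctl$peaked)
    ge <- gain_risk_gw(psi_s, env_loc, pat, hyd, T_L = T_L,
                       g0_min = ctl$g0_min)
    psi_new <- attr(ge, "psi_L")
    T_new <- solve_leaf_temperature(ge$E, env, eb)
    dd <- max(abs(T_new - T_L), abs(psi_new - psi_L))
    fac <- 1
    if (!is.null(dd_prev) && dd_prev > 0) {
      r <- dd / dd_prev
      if (is.finite(r) && r < 0.95) fac <- 1 / (1 - r)
    }
    T_L <- T_L + ctl$damping * fac * (T_new - T_L)
    psi_L <- psi_L + ctl$damping * fac * (psi_new - psi_L)
    dd_prev <- dd
    if (dd < 1e-8) break
  }
  list(gas = ge, psi_L = psi_L, T_L = T_L, E = ge$E,
       PLC = plc(psi_L, hyd), criticality = "subcritical")
}

#' One time step of the ecosystem bucket model
#'
#' Solves the canopy operating point at the current soil water
#' potential, then updates the root-zone bucket with precipitation,
#' soil evaporation and canopy transpiration.  Overflow above
#' saturation leaves as runoff; extraction below the residual content
#' is truncated and logged as a supply deficit so the water budget
#' closes exactly.
#'
#' @param state List with at least `theta` (m^3 m^-3); typically the
#'   result of a previous step (carries `plc_max` and warm-start data).
#' @param row One row of a forcing table: `time`, `precip` (mm per
#'   step), `T_air` (K), `RH`, `PPFD` (mol m^-2 s^-1), `ca`, `Patm`,
#'   `LAI`.
#' @param params List with elements `pv`, `photo`, `hyd` (per ground
#'   area), `eb`, `soil`.
#' @param dt Step length (s).
#' @param scheme `"chi_w"` or `"gainrisk"`.
#' @param control Coupler settings.
#' @return Updated state; the per-step outputs are in `state$out`.
#' @export
step_ecosystem <- function(state, row, params, dt = 1800,
                           scheme = c("chi_w", "gainrisk"),
                           control = coupler_control()) {
  scheme <- match.arg(scheme)
  soil <- params$soil
  theta <- state$theta
  psi_s <- soil_retention(theta, soil)
  env <- leaf_environment(ca = row$ca, D_L = 1, Patm = row$Patm,
                          PPFD = row$PPFD, T_air = row$T_air, RH = row$RH)
  # stomata are solved only for lit, non-freezing canopies; cold or dark
  # steps run at the cuticular floor
  daylight <- row$PPFD > 2e-5 && row$LAI > 0 && row$T_air > 276.15
  if (daylight) {
    hyd_leaf <- params$hyd
    hyd_leaf$k_max <- lai_conductance_scaling(params$hyd$k_max, row$LAI)
    env$PPFD <- light_scaling(row$PPFD, row$LAI)
    if (scheme == "chi_w") {
      op <- solve_operating_point(psi_s, env, params$photo, params$pv,
                                  hyd_leaf, params$eb, control = control,
                                  warm = state$warm)
      leaf <- list(E = op$E_demand, gw = op$gas$gw, An = op$gas$An,
                   T_L = op$T_L, psi_L = op$psi_L,
                   criticality = op$criticality,
                   energy_residual = op$energy_residual,
                   converged = op$converged &&
                     op$criticality != "desiccating")
      state$warm <- list(psi_L = op$psi_L, T_L = op$T_L)
      plc_now <- op$PLC
    } else {
      op <- solve_gainrisk_point(psi_s, env, params$photo, params$pv,
                                 hyd_leaf, params$eb, control = control,
                                 warm = state$warm)
      state$warm <- list(psi_L = op$psi_L, T_L = op$T_L)
      leaf <- list(E = op$E, gw = op$gas$gw, An = op$gas$An, T_L = op$T_L,
                   psi_L = op$psi_L, criticality = op$criticality,
                   energy_residual = leaf_energy_balance(op$T_L, op$E,
                                                         env, params$eb),
                   converged = TRUE)
      plc_now <- op$PLC
    }
  } else {
    hyd_leaf <- params$hyd
    hyd_leaf$k_max <- lai_conductance_scaling(params$hyd$k_max,
                                              max(row$LAI, 1e-3))
    leaf <- night_fluxes(psi_s, env, hyd_leaf, control$g0_min)
    if (row$LAI <= 0) leaf$E <- 0
    leaf$energy_residual <- NA_real_
    leaf$converged <- NA
    plc_now <- plc(leaf$psi_L, hyd_leaf)
  }
  cn <- params$pv$constants
  transp_m <- row$LAI * leaf$E * cn$mw / cn$rho_w * dt
  evap_m <- soil_evaporation(theta, row$T_air, row$PPFD, soil) * dt
  precip_m <- row$precip / 1000
  theta_try <- theta + (precip_m - evap_m - transp_m) / soil$Z_r
  runoff_m <- max(0, theta_try - soil$theta_sat) * soil$Z_r
  deficit_m <- max(0, soil$theta_res - theta_try) * soil$Z_r
  theta_new <- min(max(theta_try, soil$theta_res), soil$theta_sat)
  budget_err <- (theta_new - theta) * soil$Z_r -
    (precip_m - evap_m - transp_m - runoff_m + deficit_m)
  state$theta <- theta_new
  state$plc_max <- max(state$plc_max %||% 0, plc_now)
  state$out <- list(time = row$time, theta = theta_new, psi_s = psi_s,
                    gw = leaf$gw, An = leaf$An, E = leaf$E,
                    T_L = leaf$T_L, psi_L = leaf$psi_L, PLC = plc_now,
                    criticality = leaf$criticality, runoff = runoff_m,
                    deficit = deficit_m, budget_err = budget_err,
                    energy_residual = leaf$energy_residual,
                    converged = leaf$converged)
  state
}

#' Run a multi-year ecosystem simulation
#'
#' Steps the bucket model through a forcing series, collecting per-step
#' outputs and an event report: first crossing dates of the PLC
#' mortality thresholds and the set of days with supercritical leaf
#' water potentials.
#'
#' @param forcing Forcing data frame (see [step_ecosystem()]); time
#'   stamps must be strictly increasing and equally spaced.
#' @param params Parameter list (`pv`, `photo`, `hyd`, `eb`, `soil`).
#' @param theta0 Initial soil water content (defaults to 90% of
#'   saturation).
#' @param scheme Stomatal scheme.
#' @param plc_thresholds PLC mortality thresholds (percent).
#' @param control Coupler settings.
#' @param progress Print occasional progress lines?
#' @return Object of class `ecosystem_run`: list with `series` (a data
#'   frame) and `events` (mortality dates per threshold, supercritical
#'   days, cumulative water-budget error in m).
#' @export
run_simulation <- function(forcing, params, theta0 = NULL,
                           scheme = c("chi_w", "gainrisk"),
                           plc_thresholds = c(50, 85),
                           control = coupler_control(),
                           progress = FALSE) {
  scheme <- match.arg(scheme)
  stopifnot(nrow(forcing) > 1)
  tt <- as.numeric(forcing$time)
  dts <- diff(tt)
  if (any(dts <= 0)) stop("forcing time stamps must be increasing")
  dt <- stats::median(dts)
  soil <- params$soil
  state <- list(theta = theta0 %||% (0.9 * soil$theta_sat), plc_max = 0)
  n <- nrow(forcing)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    state <- step_ecosystem(state, forcing[i, ], params, dt = dt,
                            scheme = scheme, control = control)
    out[[i]] <- state$out
    if (progress && i %% 5000 == 0) {
      message(sprintf("  step %d / %d (theta %.3f)", i, n, state$theta))
    }
  }
  series <- do.call(rbind, lapply(out, function(o) {
    data.frame(time = o$time, theta = o$theta, psi_s = o$psi_s, gw = o$gw,
               An = o$An, E = o$E, T_L = o$T_L, psi_L = o$psi_L,
               PLC = o$PLC, criticality = o$criticality,
               runoff = o$runoff, deficit = o$deficit,
               budget_err = o$budget_err,
               energy_residual = o$energy_residual,
               converged = o$converged)
  }))
  events <- list(scheme = scheme)
  for (th in plc_thresholds) {
    idx <- which(series$PLC >= th)
    events[[paste0("mortality_plc", th)]] <-
      if (length(idx)) as.Date(series$time[idx[1]]) else as.Date(NA)
  }
  supercrit <- series$criticality != "subcritical"
  events$supercritical_days <- unique(as.Date(series$time[supercrit]))
  events$max_budget_err <- max(abs(series$budget_err))
  events$cumulative_budget_err <- sum(series$budget_err)
  structure(list(series = series, events = events,
                 plc_thresholds = plc_thresholds),
            class = "ecosystem_run")
}

#' @export
print.ecosystem_run <- function(x, ...) {
  cat(sprintf("Ecosystem run [%s]: %d steps\n", x$events$scheme,
              nrow(x$series)))
  for (th in x$plc_thresholds) {
    d <- x$events[[paste0("mortality_plc", th)]]
    cat(sprintf("  PLC %d%% crossing: %s\n", th,
                if (is.na(d)) "never" else format(d)))
  }
  cat(sprintf("  supercritical days: %d\n",
              length(x$events$supercritical_days)))
  invisible(x)
}

#' Compare mortality timing between two simulation reports
#'
#' Signed day differences (`a` minus `b`) of the first PLC-threshold
#' crossing dates of two runs on identical forcing; runs that never
#' cross are reported as censored.
#'
#' @param report_a,report_b `ecosystem_run` objects (or their `events`).
#' @return Data frame with threshold, both dates, the signed difference
#'   in days, and a `censored` flag.
#' @export
mortality_compare <- function(report_a, report_b) {
  ev_a <- if (inherits(report_a, "ecosystem_run")) report_a$events else report_a
  ev_b <- if (inherits(report_b, "ecosystem_run")) report_b$events else report_b
  ths <- sort(unique(c(
    as.integer(sub("mortality_plc", "",
                   grep("^mortality_plc", names(ev_a), value = TRUE))),
    as.integer(sub("mortality_plc", "",
                   grep("^mortality_plc", names(ev_b), value = TRUE))))))
  rows <- lapply(ths, function(th) {
    da <- ev_a[[paste0("mortality_plc", th)]]
    db <- ev_b[[paste0("mortality_plc", th)]]
    cens <- is.na(da) || is.na(db)
    data.frame(threshold = th, date_a = da, date_b = db,
               diff_days = if (cens) NA_real_
                           else as.numeric(da - db),
               censored = cens)
  })
  do.call(rbind, rows)
}
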