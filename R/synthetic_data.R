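# Run code under a temporary RNG state so generators never disturb the
# caller's random stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Canonical fixture parameter set
#'
#' The single parameter set used across the documentation and the test
#' suite: a conifer-like leaf whose traits lie inside the calibration
#' prior ranges and pass the wilting-closure filter (stomata shut to
#' under 5% of their full-hydration conductance at the turgor-loss
#' point under the reference environment).
#'
#' @return List with elements `pv`, `photo`, `hyd` (per leaf area),
#'   `hyd_ground` (per ground area, for the ecosystem bucket), `eb`,
#'   `soil`.
#' @export
fixture_params <- function() {
  list(
    pv = leaf_pv_params(af_max = 0.5, pi_L_star = -2.45, beta = 5,
                        eps_L0 = 5.2, SWC_L = 1.4, alpha = 2.3,
                        pi_L0_25 = -1.8, c_DM = 500),
    photo = photo_params(Vcmax25 = 80e-6, Rd25 = 0.4e-6,
                         dS_Vcmax = 620, dS_Jmax = 627,
                         sf = 2, psi_f = -2.5),
    hyd = hydraulic_params(k_max = 0.010, d_k = 1.2, Q10 = 2),
    hyd_ground = hydraulic_params(k_max = 0.035, d_k = 2.6, Q10 = 2),
    eb = energy_balance_params(Q_abs = 150, g_bH = 1.5),
    soil = soil_params()
  )
}

# Vectorized model prediction of stomatal conductance for an
# observation table, by treatment, through the calibration pathway
# (capacities taken as given, no water-stress downregulation; the
# marginal cost alone closes the stomata).
predict_gw_table <- function(data, pv_by_treatment, photo, g0_min = 0.005) {
  gw <- numeric(nrow(data))
  An <- numeric(nrow(data))
  ok <- rep(TRUE, nrow(data))
  for (tr in names(pv_by_treatment)) {
    idx <- which(data$treatment == tr)
    if (!length(idx)) next
    pv <- pv_by_treatment[[tr]]
    d <- data[idx, ]
    feas <- d$psi_L <= 0 & d$D_L > 0
    pi_L <- pi_from_psi(pmin(d$psi_L, 0), d$T_leaf, pv, extend = TRUE)
    af <- apoplastic_fraction(pi_L, pv)
    RWC <- rwc_from_pi(pi_L, d$T_leaf, pv)
    chi <- chi_w_closed_vec(pi_L, RWC, af, d$T_leaf, pv)
    ph <- photo
    if ("Vcmax25" %in% names(d) && !anyNA(d$Vcmax25)) {
      ph$Vcmax25 <- d$Vcmax25
      ph$Jmax25 <- if ("Jmax25" %in% names(d) && !anyNA(d$Jmax25)) {
        d$Jmax25
      } else {
        d$Vcmax25 * photo$Jmax25 / photo$Vcmax25
      }
      ph$Rd25 <- 0.015 * d$Vcmax25
    }
    pat <- photo_at_T(ph, d$T_leaf, d$PPFD)
    env <- list(ca = d$ca, D_L = d$D_L, Patm = d$Patm)
    ge <- gw_from_lambda_closed(pmax(chi, 1e-7), env, pat,
                                g0_min = g0_min)
    gw[idx] <- ifelse(feas, ge$gw, g0_min)
    An[idx] <- ifelse(feas, ge$An, 0)
    ok[idx] <- feas
  }
  list(gw = gw, An = An, feasible = ok)
}

#' Generate a synthetic leaf gas-exchange observation table
#'
#' Emulates a field/greenhouse campaign: environmental covariates are
#' drawn uniformly over typical measurement ranges, leaf water
#' potentials span full hydration down to near the turgor-loss point,
#' the model's optimal conductance is computed for each row, and
#' Gaussian observation noise is added (negatives truncated at the
#' cuticular floor, which introduces a small positive bias at low
#' conductance).  Per-treatment offsets shift the osmotic potential at
#' full hydration.
#'
#' @param n Number of rows.
#' @param seed RNG seed (mandatory; the generator is fully reproducible
#'   and restores the caller's RNG state).
#' @param params Parameter list as from [fixture_params()].
#' @param sigma Observation noise SD on gw (mol m^-2 s^-1).
#' @param treatments Named numeric vector of `pi_L0_25` offsets (MPa)
#'   per treatment.
#' @param ca,Patm Fixed CO2 mole fraction and pressure.
#' @param g0_min Truncation floor (mol m^-2 s^-1).
#' @return Data frame with columns `treatment`, `gw_obs`, `psi_L`,
#'   `T_leaf` (K), `D_L` (kPa), `ca`, `PPFD` (mol m^-2 s^-1), `Patm`,
#'   `An_obs`, plus attribute `truth` (the generating parameters).
#' @export
generate_gas_exchange <- function(n = 200, seed, params = fixture_params(),
                                  sigma = 0.02,
                                  treatments = c(control = 0,
                                                 elevated = -0.15),
                                  ca = 420e-6, Patm = 101.325,
                                  g0_min = 0.005) {
  stopifnot(!missing(seed))
  with_seed(seed, {
    pv0 <- params$pv
    pv_by <- lapply(treatments, function(off) {
      leaf_pv_params(pv0$af_max, pv0$pi_L_star, pv0$beta, pv0$eps_L0,
                     pv0$SWC_L, pv0$alpha, pv0$pi_L0_25 + off, pv0$c_DM,
                     constants = pv0$constants)
    })
    tr <- sample(names(treatments), n, replace = TRUE)
    T_leaf <- 273.15 + stats::runif(n, 15, 35)
    RH <- stats::runif(n, 0.3, 0.8)
    D_L <- pmax((1 - RH) * esat_kpa(T_leaf), 0.2)
    PPFD <- stats::runif(n, 200e-6, 2000e-6)
    psi_L <- numeric(n)
    for (trn in names(treatments)) {
      idx <- which(tr == trn)
      tlp <- wilting_point(pv_by[[trn]])$psi_tlp
      psi_L[idx] <- stats::runif(length(idx), 0.95 * tlp, -0.05)
    }
    dat <- data.frame(treatment = tr, gw_obs = NA_real_, psi_L = psi_L,
                      T_leaf = T_leaf, D_L = D_L, ca = ca, PPFD = PPFD,
                      Patm = Patm)
    pred <- predict_gw_table(dat, pv_by, params$photo, g0_min = g0_min)
    dat$gw_obs <- pmax(pred$gw + stats::rnorm(n, 0, sigma), g0_min)
    dat$An_obs <- pred$An
    attr(dat, "truth") <- list(params = params, treatments = treatments,
                               sigma = sigma, gw_model = pred$gw)
    dat
  })
}

#' Generate a multi-year half-hourly meteorological forcing series
#'
#' Sinusoidal seasonal and diurnal envelopes for air temperature and
#' light, stochastic marked-Poisson precipitation, a seasonal LAI
#' cycle, and an optional drought scenario that multiplies
#' summer precipitation of a target year and adds a heat anomaly.
#'
#' @param years Number of years (>= 2).
#' @param seed RNG seed (mandatory).
#' @param start Start date (first of January).
#' @param drought_year Index of the drought year (`NA` for none).
#' @param precip_multiplier Multiplier on summer (Jun-Aug) rain depths
#'   of the drought year.
#' @param heat_anomaly Added summer air temperature (K) in the drought
#'   year.
#' @param lai_range Seasonal LAI range (min, max).
#' @param annual_precip Target mean annual precipitation (mm) of a
#'   normal year.
#' @param ca,Patm CO2 mole fraction and pressure.
#' @return Forcing data frame with columns `time`, `precip` (mm per
#'   step), `T_air` (K), `RH`, `PPFD` (mol m^-2 s^-1), `ca`, `Patm`,
#'   `LAI`.
#' @export
generate_forcing <- function(years = 2, seed, start = as.Date("2001-01-01"),
                             drought_year = 2, precip_multiplier = 0.25,
                             heat_anomaly = 3, lai_range = c(3.2, 4.4),
                             annual_precip = 850, ca = 420e-6,
                             Patm = 101.325) {
  stopifnot(!missing(seed), years >= 2)
  with_seed(seed, {
    steps_per_day <- 48L
    n_days <- as.integer(years * 365)
    n <- n_days * steps_per_day
    time <- as.POSIXct(start, tz = "UTC") +
      (seq_len(n) - 1L) * 1800
    day <- rep(seq_len(n_days) - 1L, each = steps_per_day)
    doy <- day %% 365L + 1L
    yr <- day %/% 365L + 1L
    hour <- rep(seq(0, 23.5, by = 0.5), n_days)
    season <- sin(2 * pi * (doy - 80) / 365)
    # daylight window and solar envelope
    daylength <- 12 + 4 * season
    sunrise <- 12 - daylength / 2
    sunset <- 12 + daylength / 2
    sun <- ifelse(hour > sunrise & hour < sunset,
                  sin(pi * (hour - sunrise) / daylength), 0)
    cloud <- rep(stats::runif(n_days, 0.35, 1), each = steps_per_day)
    PPFD <- (8e-4 + 1.2e-3 * pmax(season, 0)) * sun * cloud
    # air temperature: seasonal + diurnal + day-to-day noise
    T_day <- rep(stats::rnorm(n_days, 0, 2.5), each = steps_per_day)
    T_air <- 273.15 + 8 + 9 * sin(2 * pi * (doy - 110) / 365) +
      4.5 * sun + T_day
    summer <- doy >= 152 & doy <= 243
    in_drought <- !is.na(drought_year) & yr == drought_year & summer
    T_air <- T_air + ifelse(in_drought, heat_anomaly, 0)
    RH <- pmin(pmax(0.78 - 0.012 * (T_air - 273.15 - 10) +
                      rep(stats::rnorm(n_days, 0, 0.05),
                          each = steps_per_day) -
                      ifelse(in_drought, 0.08, 0), 0.25), 0.98)
    # marked-Poisson rain: ~0.5 events/day with a summer-weighted
    # occurrence (convective season), exponential depths scaled so a
    # normal year meets the annual target
    wt <- 1 + 0.6 * pmax(sin(2 * pi * (doy - 110) / 365), 0)
    ev <- stats::rbinom(n, 1, pmin(0.5 * wt / steps_per_day, 1))
    mean_events <- 0.5 * 365 * mean(1 + 0.6 *
                                      pmax(sin(2 * pi *
                                                 ((1:365) - 110) / 365),
                                           0))
    depth <- stats::rexp(n, rate = mean_events / annual_precip)
    precip <- ev * depth * ifelse(in_drought, precip_multiplier, 1)
    LAI <- lai_range[1] + (lai_range[2] - lai_range[1]) *
      0.5 * (1 + sin(2 * pi * (doy - 130) / 365))
    data.frame(time = time, precip = precip, T_air = T_air, RH = RH,
               PPFD = PPFD, ca = ca, Patm = Patm, LAI = LAI)
  })
}
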