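# Intercellular CO2 at a prescribed stomatal conductance: solves the
# diffusion-demand coupling (gw/1.6) * (ca - ci) = An(ci) for one
# photosynthesis branch.  Returns the positive root of the quadratic.
ci_given_gw <- function(gw, ca, f0, gamma, Gamma_star, Rd) {
  g <- gw / 1.6
  A <- g
  B <- g * gamma + f0 - Rd - g * ca
  C <- -(g * ca * gamma + f0 * Gamma_star + Rd * gamma)
  disc <- pmax(B^2 - 4 * A * C, 0)
  (-B + sqrt(disc)) / (2 * A)
}

# Marginal profit for a single branch at a prescribed gw (internal).
lambda_branch <- function(gw, env, f0, gamma, Gamma_star, Rd) {
  ci <- ci_given_gw(gw, env$ca, f0, gamma, Gamma_star, Rd)
  Aprime <- f0 * (Gamma_star + gamma) / (ci + gamma)^2
  dAn_dgw <- (env$ca - ci) / (1.6 + gw / Aprime)
  list(lambda = env$Patm * dAn_dgw / env$D_L, ci = ci,
       An = an_of_ci(ci, f0, gamma, Gamma_star, Rd))
}

#' Marginal carbon profit of water at a given stomatal conductance
#'
#' `lambda = (dAn/dgw) / (dE/dgw)` with `dE/dgw = D_L / Patm` (boundary
#' layer and mesophyll resistance neglected) and `dAn/dgw` from implicit
#' differentiation of the diffusion-demand coupling
#' `An = (gw / 1.6) * (ca - ci)`.  The profit is positive and strictly
#' decreasing in `gw`; at the optimum it equals the marginal carbon
#' cost of water.
#'
#' @param gw Stomatal conductance to water vapour (mol m^-2 s^-1, > 0).
#' @param env A [leaf_environment()].
#' @param pat A [photo_at_T()] object.
#' @param branch `"auto"` (the realized minimum-An branch) or a specific
#'   branch name.
#' @return Marginal profit (mol CO2 per mol H2O).
#' @export
marginal_profit <- function(gw, env, pat,
                            branch = c("auto", "carboxylation",
                                       "electron_transport")) {
  branch <- match.arg(branch)
  if (any(gw <= 0)) stop("gw must be positive")
  lc <- lambda_branch(gw, env, pat$carboxylation$f0, pat$carboxylation$gamma,
                      pat$Gamma_star, pat$Rd)
  le <- lambda_branch(gw, env, pat$electron_transport$f0,
                      pat$electron_transport$gamma, pat$Gamma_star, pat$Rd)
  switch(branch,
         carboxylation = lc$lambda,
         electron_transport = le$lambda,
         auto = ifelse(lc$An <= le$An, lc$lambda, le$lambda))
}

# Largest attainable marginal profit for a branch (the gw -> 0 limit),
# together with the ci at which net assimilation vanishes.  Vectorized.
lambda_max_branch <- function(env, f0, gamma, Gamma_star, Rd) {
  n <- max(length(f0), length(gamma), length(Gamma_star), length(Rd),
           length(env$ca), length(env$D_L))
  f0 <- rep_len(f0, n); gamma <- rep_len(gamma, n); Rd <- rep_len(Rd, n)
  Gamma_star <- rep_len(Gamma_star, n)
  ca <- rep_len(env$ca, n); DL <- rep_len(env$D_L, n)
  Patm <- rep_len(env$Patm, n)
  ok <- f0 > Rd
  ci0 <- ifelse(ok, (f0 * Gamma_star + Rd * gamma) / pmax(f0 - Rd, 1e-300),
                NA_real_)
  lmax <- ifelse(ok & !is.na(ci0) & ci0 < ca,
                 Patm * (ca - ci0) / (1.6 * DL), 0)
  list(lambda_max = lmax, ci0 = ci0)
}

# Solve one branch for the ci at which the marginal profit equals
# lambda, in closed form.  Substituting the diffusion-demand coupling
# into the marginal condition
#   (ca - ci) = (lambda D / P) * (1.6 + gw / A'(ci))
# and normalizing by x = (ci - Gamma_star) / (ca - Gamma_star) yields a
# quadratic with the unitless shorthands
#   y = 1.6 lambda D / (P (ca - Gamma_star)),
#   z = 1.6 lambda D / (P (Gamma_star + gamma)),
#   rho = Rd / f0:
#   [1 - z (1 - rho)] x^2 - 2 [1 - rho y] x + [1 - y + rho y^2 / z] = 0.
# The optimum is the root in (x0, 1), x0 marking zero net assimilation.
# solve_branch_ci_safeguarded() solves the same marginal condition by
# bracketed search and is used as the cross-check oracle in the tests.
solve_branch_ci <- function(lambda, env, f0, gamma, Gamma_star, Rd) {
  lm <- lambda_max_branch(env, f0, gamma, Gamma_star, Rd)
  n <- max(length(lambda), length(f0), length(lm$ci0), length(env$ca),
           length(gamma), length(Gamma_star))
  lambda <- rep_len(lambda, n); f0 <- rep_len(f0, n)
  gamma <- rep_len(gamma, n); Gamma_star <- rep_len(Gamma_star, n)
  Rd <- rep_len(Rd, n)
  ca <- rep_len(env$ca, n)
  t_ <- lambda * rep_len(env$D_L, n) / rep_len(env$Patm, n)
  w <- ca - Gamma_star
  G <- Gamma_star + gamma
  y <- 1.6 * t_ / w
  z <- 1.6 * t_ / G
  rho <- Rd / pmax(f0, 1e-300)
  A2 <- 1 - z * (1 - rho)
  B1 <- 1 - rho * y
  C0 <- 1 - y + rho * y^2 / z
  disc <- B1^2 - A2 * C0
  sq <- sqrt(pmax(disc, 0))
  # quadratic roots (linear fallback when A2 ~ 0)
  xm <- (B1 - sq) / A2
  xp <- (B1 + sq) / A2
  small <- abs(A2) < 1e-12
  if (any(small)) {
    xl <- C0 / (2 * B1)
    xm[small] <- xl[small]
    xp[small] <- xl[small]
  }
  x0 <- (lm$ci0 - Gamma_star) / w
  ok_rng <- function(x) {
    o <- is.finite(x) & is.finite(x0) & x > x0 & x < 1
    o & !is.na(o)
  }
  x <- xm
  bad <- !ok_rng(x)
  if (any(bad)) {
    x[bad] <- xp[bad]
    x[!ok_rng(x)] <- NA_real_
  }
  feasible <- lambda < lm$lambda_max * (1 - 1e-12) & lm$lambda_max > 0 &
    disc >= 0 & !is.na(x)
  list(ci = Gamma_star + x * w, feasible = feasible)
}

# Safeguarded bracketed solve of the marginal condition on
# ci in (ci0, ca); independent of the closed form above.
solve_branch_ci_safeguarded <- function(lambda, env, f0, gamma,
                                        Gamma_star, Rd, iters = 80L) {
  lm <- lambda_max_branch(env, f0, gamma, Gamma_star, Rd)
  n <- max(length(lambda), length(f0), length(lm$ci0), length(env$ca))
  lambda <- rep_len(lambda, n); f0 <- rep_len(f0, n)
  gamma <- rep_len(gamma, n)
  t_ <- lambda * env$D_L / env$Patm
  resid <- function(ci) {
    An <- f0 * (ci - Gamma_star) / (ci + gamma) - Rd
    (env$ca - ci)^2 - 1.6 * t_ * (env$ca - ci) -
      1.6 * t_ * An * (ci + gamma)^2 / (f0 * (Gamma_star + gamma))
  }
  lo <- rep_len(lm$ci0 * (1 + 1e-12), n)
  hi <- rep_len(env$ca * (1 - 1e-12), n)
  ci <- bisect_vec(resid, lo, hi, iters = iters)
  feasible <- lambda < lm$lambda_max * (1 - 1e-12) & lm$lambda_max > 0
  list(ci = ci, feasible = feasible)
}

# Assemble a gas_exchange record from a solved ci for one branch.
branch_exchange <- function(ci, feasible, lambda, env, f0, gamma,
                            Gamma_star, Rd, g0_min, gw_cap) {
  bad <- !is.finite(ci)
  if (any(bad)) ci[bad] <- rep_len(env$ca, length(ci))[bad]
  An <- an_of_ci(pmax(ci, 1e-12), f0, gamma, Gamma_star, Rd)
  gw <- 1.6 * An / (env$ca - ci)
  gw[!(feasible & is.finite(gw))] <- g0_min
  gw <- pmin(pmax(gw, g0_min), gw_cap)
  ci <- ci_given_gw(gw, env$ca, f0, gamma, Gamma_star, Rd)
  An <- an_of_ci(ci, f0, gamma, Gamma_star, Rd)
  list(gw = gw, An = An, ci = ci, closed = !feasible)
}

#' Optimal stomatal conductance from a marginal water price
#'
#' Inverts the marginal-profit relation: returns the stomatal
#' conductance at which `marginal_profit(gw) = lambda`, solved per
#' photosynthesis branch on the normalized intercellular CO2
#' `x = (ci - Gamma_star) / (ca - Gamma_star)` in (0, 1) and combined by
#' the minimum-assimilation rule (ties toward carboxylation).  When
#' `lambda` meets or exceeds the largest attainable profit the stomata
#' close onto the cuticular floor `g0_min` and the result is flagged.
#'
#' @param lambda Marginal carbon cost of water (mol CO2 per mol H2O,
#'   > 0).
#' @param env A [leaf_environment()].
#' @param pat A [photo_at_T()] object.
#' @param g0_min Cuticular conductance floor (mol m^-2 s^-1).
#' @param gw_cap Upper clamp on conductance (mol m^-2 s^-1).
#' @return An object of class `gas_exchange`: list with `gw`, `An`, `E`,
#'   `ci`, `x`, `limitation`, `lambda_used`, `closed`.
#' @export
gw_from_lambda_closed <- function(lambda, env, pat, g0_min = 0.005,
                                  gw_cap = 5) {
  if (any(lambda <= 0)) stop("lambda must be positive")
  cb <- pat$carboxylation; et <- pat$electron_transport
  sc <- solve_branch_ci(lambda, env, cb$f0, cb$gamma, pat$Gamma_star, pat$Rd)
  se <- solve_branch_ci(lambda, env, et$f0, et$gamma, pat$Gamma_star, pat$Rd)
  bc <- branch_exchange(sc$ci, sc$feasible, lambda, env, cb$f0, cb$gamma,
                        pat$Gamma_star, pat$Rd, g0_min, gw_cap)
  be <- branch_exchange(se$ci, se$feasible, lambda, env, et$f0, et$gamma,
                        pat$Gamma_star, pat$Rd, g0_min, gw_cap)
  n <- max(length(bc$gw), length(be$gw))
  min_an_at <- function(gw) {
    cc <- ci_given_gw(gw, env$ca, cb$f0, cb$gamma, pat$Gamma_star, pat$Rd)
    ce <- ci_given_gw(gw, env$ca, et$f0, et$gamma, pat$Gamma_star, pat$Rd)
    pmin(an_of_ci(cc, cb$f0, cb$gamma, pat$Gamma_star, pat$Rd),
         an_of_ci(ce, et$f0, et$gamma, pat$Gamma_star, pat$Rd))
  }
  lamEP <- lambda * env$D_L / env$Patm
  # The realized assimilation is the minimum of the two branches, so
  # the profit-maximizing conductance is the best of three candidates:
  # each branch optimum (valid where its own branch is the limiting
  # one) and the co-limitation kink where the branches cross.
  obj_c <- min_an_at(bc$gw) - lamEP * bc$gw
  obj_e <- min_an_at(be$gw) - lamEP * be$gw
  valid_c <- !bc$closed & abs(min_an_at(bc$gw) - bc$An) < 1e-12 +
    1e-9 * abs(bc$An)
  valid_e <- !be$closed & abs(min_an_at(be$gw) - be$An) < 1e-12 +
    1e-9 * abs(be$An)
  # branch-crossing ci (closed form) and the kink conductance
  df0 <- rep_len(cb$f0 - et$f0, n)
  ci_x <- (rep_len(et$f0, n) * rep_len(cb$gamma, n) -
             rep_len(cb$f0, n) * rep_len(et$gamma, n)) /
    ifelse(abs(df0) > 1e-300, df0, 1e-300)
  an_x <- an_of_ci(pmax(ci_x, 1e-12), cb$f0, cb$gamma, pat$Gamma_star,
                   pat$Rd)
  gw_x <- 1.6 * an_x / (rep_len(env$ca, n) - ci_x)
  obj_x <- an_x - lamEP * gw_x
  # the kink is an admissible optimum only when opening that far beats
  # staying closed at the cuticular floor
  obj_floor <- min_an_at(rep_len(g0_min, n)) - lamEP * g0_min
  valid_x <- is.finite(gw_x) & ci_x > pat$Gamma_star &
    ci_x < rep_len(env$ca, n) & an_x > 0 & gw_x > g0_min & gw_x < gw_cap &
    obj_x > obj_floor
  obj_x[!valid_x] <- -Inf
  obj_c[!valid_c] <- -Inf
  obj_e[!valid_e] <- -Inf
  # choose the best candidate; ties and all-invalid go to closure on
  # the carboxylation record
  pick_e <- valid_e & (obj_e > obj_c + 1e-18) & (obj_e >= obj_x)
  pick_x <- valid_x & (obj_x > obj_c + 1e-18) & (obj_x > obj_e + 1e-18) &
    !pick_e
  gw <- rep_len(bc$gw, n); ci <- rep_len(bc$ci, n)
  An <- rep_len(bc$An, n); closed <- rep_len(bc$closed, n)
  lim <- rep("carboxylation", n)
  closed <- closed & !valid_e & !valid_x   # any valid candidate opens
  gw[pick_e] <- rep_len(be$gw, n)[pick_e]
  ci[pick_e] <- rep_len(be$ci, n)[pick_e]
  An[pick_e] <- rep_len(be$An, n)[pick_e]
  closed[pick_e] <- FALSE
  lim[pick_e] <- "electron_transport"
  gw[pick_x] <- gw_x[pick_x]
  ci[pick_x] <- ci_x[pick_x]
  An[pick_x] <- an_x[pick_x]
  closed[pick_x] <- FALSE
  lim[pick_x] <- "co-limited"
  structure(list(
    gw = gw, An = An, E = gw * env$D_L / env$Patm, ci = ci,
    x = (ci - pat$Gamma_star) / (env$ca - pat$Gamma_star),
    limitation = lim,
    lambda_used = lambda, closed = closed), class = "gas_exchange")
}

#' @export
print.gas_exchange <- function(x, ...) {
  cat(sprintf(
    "Gas exchange: gw %.4f mol/m2/s  An %.3g  E %.3g  ci/ca-x %.3f  %s%s\n",
    x$gw[1], x$An[1], x$E[1], x$x[1], x$limitation[1],
    if (isTRUE(x$closed[1])) "  [closed]" else ""))
  invisible(x)
}

#' Optimal gas exchange for a leaf state
#'
#' The full pipeline of the optimality scheme: the marginal carbon cost
#' of water is computed from the leaf state ([chi_w_closed()]), equated
#' to the marginal profit, and inverted to the optimal stomatal
#' conductance ([gw_from_lambda_closed()]) with photosynthetic
#' capacities resolved at the leaf temperature (and, optionally,
#' downregulated by the sigmoidal water-stress response).
#'
#' @param state A `leaf_state`.
#' @param env A [leaf_environment()].
#' @param photo A [photo_params()] object.
#' @param pv A [leaf_pv_params()] object.
#' @param water_stress Apply the sigmoidal capacity downregulation at
#'   the state's water potential?  Disable when capacities were
#'   estimated independently of water status (as in calibration).
#' @param peaked Use the peaked capacity-temperature response?
#' @param g0_min,gw_cap Conductance floor and cap (mol m^-2 s^-1).
#' @param lambda_floor Lower clamp on the water price: states in which
#'   the concentration benefit of transpiration exceeds its cooling cost
#'   would otherwise price water at or below zero.
#' @return A `gas_exchange` object.
#' @export
optimal_gas_exchange <- function(state, env, photo, pv,
                                 water_stress = TRUE, peaked = FALSE,
                                 g0_min = 0.005, gw_cap = 5,
                                 lambda_floor = 1e-7) {
  chi <- chi_w_closed(state, pv, strict = FALSE)
  pat <- photo_at_T(photo, state$T_LK, env$PPFD,
                    psi_L = if (water_stress) state$psi_L else NULL,
                    peaked = peaked)
  gw_from_lambda_closed(max(chi, lambda_floor), env, pat,
                        g0_min = g0_min, gw_cap = gw_cap)
}

#' VPD sensitivity of stomatal conductance (the m metric)
#'
#' Least-squares fit of `gw = a + b * ln(D_L)`; the sensitivity is
#' `m = -b / a`, the slope normalized by the fitted conductance at
#' `D_L = 1` kPa, sign-flipped so that closure with rising VPD gives
#' `m > 0`.
#'
#' @param D_L Vapour pressure deficits (kPa); at least 5 points spanning
#'   the 1-3 kPa range.
#' @param gw Stomatal conductances (mol m^-2 s^-1).
#' @return The unitless sensitivity m.
#' @export
vpd_sensitivity_m <- function(D_L, gw) {
  if (length(D_L) < 5 || length(gw) != length(D_L)) {
    stop("need >= 5 (D_L, gw) pairs")
  }
  if (min(D_L) > 1.1 || max(D_L) < 2.9) {
    stop("the gw curve must span at least the 1-3 kPa VPD range")
  }
  X <- cbind(1, log(D_L))
  fit <- stats::lm.fit(X, gw)
  a <- fit$coefficients[1]; b <- fit$coefficients[2]
  if (!is.finite(a) || abs(a) < 1e-12) {
    stop("degenerate gw curve: fitted gw at D_L = 1 kPa is zero")
  }
  unname(-b / a)
}
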