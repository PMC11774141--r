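# Independent oracle for pi_dot: explicit central-difference integration
# of the leaf water / solute / heat stocks, re-solving the van't Hoff
# constraint for pi_L at each perturbed stock state.
euler_pi_dot <- function(An, E, state, pv, lma = 0.1, dt = 1e-4) {
  cn <- pv$constants
  V_sat <- pv$SWC_L * lma / cn$rho_w
  W0 <- state$RWC_LT * V_sat
  ns0 <- -state$pi_L * (state$RWC_LT - state$a_f) * V_sat /
    (cn$varpi * cn$R * state$T_LK)
  rates <- function(s) {
    C_heat <- (pv$SWC_L * (s[1] / V_sat) * cn$cw + pv$c_DM) * lma
    c(-E * cn$mw / cn$rho_w, An / pv$alpha,
      -latent_heat(s[3]) * cn$mw * E / C_heat)
  }
  pi_of <- function(s) {
    f <- function(p) {
      p * (s[1] / V_sat - apoplastic_fraction(p, pv)) * V_sat +
        cn$varpi * cn$R * s[3] * s[2]
    }
    stats::uniroot(f, c(-200, -1e-10), tol = 1e-14)$root
  }
  s0 <- c(W0, ns0, state$T_LK)
  sp <- s0 + dt * rates(s0)
  sm <- s0 - dt * rates(s0)
  (pi_of(sp) - pi_of(sm)) / (2 * dt)
}

test_that("latent heat of vaporization follows the linear formula", {
  expect_equal(latent_heat(273.15), 2.501e6)
  expect_equal(latent_heat(298.15), 2441750)
  expect_equal(latent_heat(318.15), 2394350)
  expect_error(latent_heat(220), "range")
})

test_that("pi_dot matches explicit stock integration and has the right signs", {
  pv <- fx$pv
  st <- state_from_psi(-0.8, 298.15, pv)
  expect_equal(pi_dot(0, 0, st, pv), 0)
  expect_lt(pi_dot(1e-5, 0, st, pv), 0)  # pure solute addition
  for (fl in list(c(1e-5, 2e-3), c(5e-6, 5e-4), c(0, 1e-3))) {
    expect_equal(pi_dot(fl[1], fl[2], st, pv),
                 euler_pi_dot(fl[1], fl[2], st, pv),
                 tolerance = 1e-6)
  }
})

test_that("the finite-difference cost is flux-point and step independent", {
  pv <- fx$pv
  st <- state_from_psi(-1.2, 303.15, pv)
  c0 <- chi_w_numeric(st, pv)
  expect_equal(chi_w_numeric(st, pv, An0 = 1e-5, E0 = 2e-3), c0,
               tolerance = 1e-5)
  expect_equal(chi_w_numeric(st, pv, rel_step = 1e-6), c0,
               tolerance = 1e-9)
  # doubling alpha halves |d pi_dot / d An| and doubles the cost
  pv2 <- leaf_pv_params(pv$af_max, pv$pi_L_star, pv$beta, pv$eps_L0,
                        pv$SWC_L, 2 * pv$alpha, pv$pi_L0_25, pv$c_DM)
  st2 <- state_from_psi(-1.2, 303.15, pv2)
  expect_equal(chi_w_numeric(st2, pv2), 2 * c0, tolerance = 1e-7)
})

test_that("closed-form cost equals the mechanistic finite-difference oracle", {
  pv <- fx$pv
  for (rwc in c(0.85, 0.92, 1)) {
    for (T in c(285.15, 298.15, 313.15)) {
      st <- stomopt:::leaf_state_from_pi(osmotic_potential(rwc, T, pv),
                                         T, pv)
      expect_equal(chi_w_closed(st, pv, strict = FALSE),
                   chi_w_numeric(st, pv), tolerance = 1e-9)
    }
  }
})

test_that("the cost responds to temperature, hydration and pi_L0 as the physics demands", {
  pv <- fx$pv
  # cooler leaves price water higher (fixed hydration)
  for (rwc in c(1, 0.9)) {
    chis <- vapply(seq(288.15, 318.15, by = 2.5), function(T) {
      st <- stomopt:::leaf_state_from_pi(osmotic_potential(rwc, T, pv),
                                         T, pv)
      chi_w_closed(st, pv)
    }, 0)
    expect_true(all(diff(chis) < 0))
  }
  # dehydration toward the wilting point raises the cost
  wp <- wilting_point(pv, 298.15)
  rwcs <- seq(1, wp$RWC_tlp, length.out = 20)
  chis <- vapply(rwcs, function(r) {
    st <- stomopt:::leaf_state_from_pi(osmotic_potential(r, 298.15, pv),
                                       298.15, pv)
    chi_w_closed(st, pv)
  }, 0)
  expect_gt(chis[20], 4 * chis[1])
  # carbon-use feedback: more negative pi_L0 raises the cost
  st_ref <- state_from_psi(-0.5, 298.15, pv)
  chi_ref <- chi_w_closed(st_ref, pv)
  pv2 <- leaf_pv_params(pv$af_max, pv$pi_L_star, pv$beta, pv$eps_L0,
                        pv$SWC_L, pv$alpha, pv$pi_L0_25 - 0.3, pv$c_DM)
  st2 <- state_from_psi(-0.5, 298.15, pv2)
  expect_gt(chi_w_closed(st2, pv2), chi_ref)
})

test_that("the strict closed form flags negative costs as convention bugs", {
  pv <- fx$pv
  # extreme dehydration deep past the wilting point prices water
  # negatively (concentration benefit exceeds the cooling cost)
  st <- stomopt:::state_from_psi_any(-45, 298.15, pv)
  expect_lt(chi_w_closed(st, pv, strict = FALSE), 0)
  expect_error(chi_w_closed(st, pv, strict = TRUE), "inconsistency")
})

test_that("the apoplast-feedback shorthand Delta evaluates as printed", {
  # construct af_0 = 0.2 exactly: af_max * exp(-(1.8/pi_star)^2) = 0.2
  pi_star <- -1.8 / sqrt(-log(0.2 / 0.25))
  p <- leaf_pv_params(af_max = 0.25, pi_L_star = pi_star, beta = 2,
                      eps_L0 = 12, SWC_L = 2, alpha = 3, pi_L0_25 = -1.8)
  pi_L <- pi_star * sqrt(0.25)      # (pi_L / pi_star)^beta = 0.25
  st <- stomopt:::leaf_state_from_pi(pi_L, 298.15, p)
  expect_equal(delta_term(st, p),
               1 - (12 / 13.8) * 2 * 0.25 * 0.25, tolerance = 1e-9)
  # rigid-apoplast limit: Delta -> 1
  p0 <- leaf_pv_params(af_max = 1e-9, pi_L_star = -3, beta = 2,
                       eps_L0 = 12, SWC_L = 2, alpha = 3, pi_L0_25 = -1.8)
  st0 <- stomopt:::leaf_state_from_pi(-2, 298.15, p0)
  expect_equal(delta_term(st0, p0), 1, tolerance = 1e-8)
  # Delta declines as the symplast concentrates
  pis <- seq(-1.9, -4, by = -0.1)
  deltas <- vapply(pis, function(pp) {
    delta_term(stomopt:::leaf_state_from_pi(pp, 298.15, p), p)
  }, 0)
  expect_true(all(diff(deltas) < 0))
})
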