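test_that("marginal profit is positive, decreasing, and matches finite differences", {
  pat <- photo_at_T(fx$photo, 298.15, ref_env$PPFD)
  gws <- c(0.01, 0.05, 0.1, 0.3, 1)
  lams <- marginal_profit(gws, ref_env, pat)
  expect_true(all(lams > 0))
  expect_true(all(diff(lams) < 0))
  # finite-difference oracle dAn/dE along gw for each branch
  h <- 1e-7
  for (br in c("carboxylation", "electron_transport")) {
    b <- pat[[br]]
    an_of_gw <- function(gw) {
      ci <- stomopt:::ci_given_gw(gw, ref_env$ca, b$f0, b$gamma,
                                  pat$Gamma_star, pat$Rd)
      an_of_ci(ci, b$f0, b$gamma, pat$Gamma_star, pat$Rd)
    }
    for (gw in c(0.05, 0.2)) {
      lam_fd <- (an_of_gw(gw + h) - an_of_gw(gw - h)) /
        ((2 * h) * ref_env$D_L / ref_env$Patm)
      expect_equal(marginal_profit(gw, ref_env, pat, branch = br), lam_fd,
                   tolerance = 1e-6)
    }
  }
  # saturation: profit vanishes at very large gw
  expect_lt(marginal_profit(50, ref_env, pat), lams[1] / 50)
  expect_error(marginal_profit(-0.1, ref_env, pat), "positive")
})

test_that("closed-form conductance equals the safeguarded marginal-condition root", {
  set.seed(31)
  for (i in 1:60) {
    env <- leaf_environment(ca = runif(1, 300e-6, 700e-6),
                            D_L = runif(1, 0.3, 4),
                            PPFD = runif(1, 2e-4, 2e-3),
                            T_air = runif(1, 280, 315))
    pat <- photo_at_T(fx$photo, env$T_air, env$PPFD)
    for (br in c("carboxylation", "electron_transport")) {
      b <- pat[[br]]
      lmax <- stomopt:::lambda_max_branch(env, b$f0, b$gamma,
                                          pat$Gamma_star,
                                          pat$Rd)$lambda_max
      lam <- runif(1, 0.05, 0.9) * lmax
      s1 <- stomopt:::solve_branch_ci(lam, env, b$f0, b$gamma,
                                      pat$Gamma_star, pat$Rd)
      s2 <- stomopt:::solve_branch_ci_safeguarded(lam, env, b$f0, b$gamma,
                                                  pat$Gamma_star, pat$Rd)
      expect_equal(s1$feasible, s2$feasible)
      expect_equal(s1$ci, s2$ci, tolerance = 1e-10)
    }
  }
})

test_that("the lambda-to-gw map inverts the marginal profit and closes at high prices", {
  pat <- photo_at_T(fx$photo, 298.15, ref_env$PPFD)
  for (lam in c(2e-4, 1e-3, 4e-3, 9e-3)) {
    ge <- gw_from_lambda_closed(lam, ref_env, pat)
    expect_false(ge$closed)
    if (ge$limitation == "co-limited") {
      # at the co-limitation kink the one-sided marginal profits
      # bracket the imposed price
      l_lo <- marginal_profit(ge$gw * (1 + 1e-6), ref_env, pat)
      l_hi <- marginal_profit(ge$gw * (1 - 1e-6), ref_env, pat)
      expect_lte(min(l_lo, l_hi), lam * (1 + 1e-6))
      expect_gte(max(l_lo, l_hi), lam * (1 - 1e-6))
      next
    }
    expect_equal(marginal_profit(ge$gw, ref_env, pat,
                                 branch = ge$limitation), lam,
                 tolerance = 1e-8)
    expect_equal(ge$E, ge$gw * ref_env$D_L / ref_env$Patm,
                 tolerance = 1e-15)
    expect_true(ge$x > 0 && ge$x < 1)
  }
  # inverse consistency: lambda measured at a known gw* is mapped back
  for (gw_star in c(0.03, 0.12, 0.4)) {
    lam <- marginal_profit(gw_star, ref_env, pat)
    ge <- gw_from_lambda_closed(lam, ref_env, pat)
    expect_equal(ge$gw, gw_star, tolerance = 1e-8)
  }
  # infinite water price closes the stomata onto the cuticular floor
  ge_hi <- gw_from_lambda_closed(0.5, ref_env, pat)
  expect_true(ge_hi$closed)
  expect_equal(ge_hi$gw, 0.005)
  # gw strictly decreasing in lambda
  gws <- vapply(c(2e-4, 5e-4, 1e-3, 2e-3, 4e-3, 8e-3),
                function(l) gw_from_lambda_closed(l, ref_env, pat)$gw, 0)
  expect_true(all(diff(gws) < 0))
})

test_that("closed form equals the golden-section optimization oracle", {
  set.seed(99)
  for (i in 1:40) {
    env <- leaf_environment(ca = runif(1, 320e-6, 600e-6),
                            D_L = runif(1, 0.5, 3.5),
                            PPFD = runif(1, 3e-4, 2e-3),
                            T_air = runif(1, 283, 313))
    pat <- photo_at_T(fx$photo, env$T_air, env$PPFD)
    lam <- runif(1, 3e-4, 6e-3)
    ge <- gw_from_lambda_closed(lam, env, pat)
    if (ge$closed || ge$gw > 1.9) next
    oracle <- gw_optimization_oracle(lam, env, pat)
    expect_equal(ge$gw, oracle, tolerance = 1e-6)
  }
})

test_that("optimal gas exchange responds to hydration, temperature and pi_L0 as observed", {
  pv <- fx$pv; ph <- fx$photo
  wp <- wilting_point(pv, 298.15)
  ge_full <- optimal_gas_exchange(state_from_psi(-1e-9, 298.15, pv),
                                  ref_env, ph, pv, water_stress = FALSE)
  ge_tlp <- optimal_gas_exchange(state_from_psi(wp$psi_tlp, 298.15, pv),
                                 ref_env, ph, pv, water_stress = FALSE)
  expect_lte(ge_tlp$gw, 0.05 * ge_full$gw)
  # warmer leaves open stomata when well hydrated
  ge_cold <- optimal_gas_exchange(state_from_psi(-0.2, 290.15, pv),
                                  ref_env, ph, pv, water_stress = FALSE)
  ge_warm <- optimal_gas_exchange(state_from_psi(-0.2, 306.15, pv),
                                  ref_env, ph, pv, water_stress = FALSE)
  expect_gt(ge_warm$gw, ge_cold$gw)
  # accumulating carbohydrates (more negative pi_L0) close stomata
  pv2 <- leaf_pv_params(pv$af_max, pv$pi_L_star, pv$beta, pv$eps_L0,
                        pv$SWC_L, pv$alpha, pv$pi_L0_25 - 0.3, pv$c_DM)
  ge_sweet <- optimal_gas_exchange(state_from_psi(-0.2, 298.15, pv2),
                                   ref_env, ph, pv2, water_stress = FALSE)
  ge_ref <- optimal_gas_exchange(state_from_psi(-0.2, 298.15, pv),
                                 ref_env, ph, pv, water_stress = FALSE)
  expect_lt(ge_sweet$gw, ge_ref$gw)
})

test_that("the VPD sensitivity metric recovers constructed slopes", {
  D <- seq(1, 3, length.out = 9)
  expect_equal(vpd_sensitivity_m(D, 0.2 * (1 - 0.6 * log(D))), 0.6,
               tolerance = 1e-12)
  expect_equal(vpd_sensitivity_m(D, rep(0.15, 9)), 0)
  # regression oracle for a D^(-1/2) curve: independent least-squares
  gw <- 0.2 * D^(-0.5)
  fit <- stats::lm(gw ~ log(D))
  m_oracle <- -unname(coef(fit)[2] / coef(fit)[1])
  expect_equal(vpd_sensitivity_m(D, gw), m_oracle, tolerance = 1e-12)
  expect_error(vpd_sensitivity_m(D[1:3], gw[1:3]), ">= 5")
  expect_error(vpd_sensitivity_m(seq(1.5, 2.5, length.out = 6),
                                 rep(0.1, 6)), "span")
})
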