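test_that("hydraulic conductance and supply follow the exponential model", {
  hyd <- hydraulic_params(k_max = 2e-3, d_k = 1.5, Q10 = 2,
                          T_ref = 298.15)
  expect_equal(conductance(0, 298.15, hyd), 2e-3)
  expect_equal(conductance(-1.5, 298.15, hyd), 2e-3 * exp(-1))
  expect_equal(conductance(-1, 308.15, hyd), 0.00205366847613,
               tolerance = 1e-10)
  expect_equal(supply(-0.2, -0.2, 298.15, hyd), 0)
  expect_equal(supply(-0.2, -1.2, 298.15, hyd),
               conductance(-1.2, 298.15, hyd) * 1)
  expect_lt(supply(-0.2, -40, 298.15, hyd), 1e-12)
  expect_error(supply(-1, -0.5, 298.15, hyd), "gradient")
})

test_that("the critical point matches numeric maximization of supply", {
  hyd <- hydraulic_params(k_max = 1, d_k = 1, Q10 = 1, T_ref = 298.15)
  cp <- critical_point(0, 298.15, hyd)
  expect_equal(cp$psi_crit, -1)
  expect_equal(cp$E_crit, exp(-1))
  # grid-scan oracle
  psis <- seq(-6, -1e-6, length.out = 1e6)
  E <- supply(0, psis, 298.15, hyd)
  expect_equal(cp$psi_crit, psis[which.max(E)], tolerance = 1e-5)
  expect_equal(cp$E_crit, max(E), tolerance = 1e-9)
  # translation invariance and k_max homogeneity
  cp2 <- critical_point(-0.7, 298.15, hyd)
  expect_equal(cp2$psi_crit, cp$psi_crit - 0.7)
  hyd3 <- hydraulic_params(k_max = 3, d_k = 1, Q10 = 1, T_ref = 298.15)
  expect_equal(critical_point(0, 298.15, hyd3)$E_crit, 3 * cp$E_crit)
})

test_that("percent loss of conductance inverts the vulnerability curve", {
  hyd <- fx$hyd
  expect_equal(plc(0, hyd), 0)
  expect_equal(plc(-hyd$d_k * log(2), hyd), 50)
  expect_equal(plc(-hyd$d_k * log(1 / 0.15), hyd), 85)
  expect_true(all(plc(seq(0, -30, by = -0.5), hyd) < 100))
})

test_that("leaf energy balance has a unique root matching a grid scan", {
  eb <- fx$eb
  env <- leaf_environment(T_air = 298.15, RH = 0.5)
  # no radiation load, no transpiration: leaf sits at air temperature
  eb0 <- energy_balance_params(Q_abs = 0, g_bH = eb$g_bH)
  expect_equal(solve_leaf_temperature(0, env, eb0), env$T_air)
  expect_equal(leaf_energy_balance(env$T_air, 0, env, eb0), 0)
  # transpiration cools: higher E lowers the residual at fixed T_L
  r1 <- leaf_energy_balance(300, 1e-3, env, eb)
  r2 <- leaf_energy_balance(300, 3e-3, env, eb)
  expect_lt(r2, r1)
  # residual is strictly decreasing in T_L; root matches a fine scan
  Ts <- seq(290, 310, by = 1e-4)
  res <- leaf_energy_balance(Ts, 2e-3, env, eb)
  expect_true(all(diff(res) < 0))
  T_root <- solve_leaf_temperature(2e-3, env, eb)
  expect_equal(T_root, Ts[which.min(abs(res))], tolerance = 2e-4)
  expect_lt(abs(leaf_energy_balance(T_root, 2e-3, env, eb)), 1e-9)
})

test_that("the coupled operating point closes both balances to tolerance", {
  op <- cached("op_mild", {
    solve_operating_point(-0.3, leaf_environment(T_air = 298.15,
                                                 RH = 0.5),
                          fx$photo, fx$pv, fx$hyd, fx$eb)
  })
  expect_identical(op$criticality, "subcritical")
  expect_lt(abs(op$mismatch), 1e-9)
  expect_lt(abs(op$energy_residual), 1e-6)
  expect_gt(op$psi_L, op$psi_crit)
  expect_gt(op$gas$gw, 0.02)
  # state consistency: reported leaf state reproduces psi_L
  expect_equal(op$state$psi_L, op$psi_L, tolerance = 1e-8)
})

test_that("root classification distinguishes supercritical and desiccating regimes", {
  # tiny supply: demand exceeds the whole supply curve -> desiccation
  hyd_weak <- hydraulic_params(k_max = 1e-5, d_k = 1.2, Q10 = 2)
  env <- leaf_environment(T_air = 303.15, RH = 0.35)
  op_d <- solve_operating_point(-0.5, env, fx$photo, fx$pv, hyd_weak,
                                fx$eb)
  expect_identical(op_d$criticality, "desiccating")
  expect_lt(op_d$E_supply, op_d$E_demand)
  # moderate drought with intermediate supply: demand intersects only
  # the falling branch -> stable supercritical operating point
  hyd_mid <- hydraulic_params(k_max = 1.2e-3, d_k = 0.8, Q10 = 2)
  op_s <- cached("op_super", {
    solve_operating_point(-0.7, env, fx$photo, fx$pv, hyd_mid, fx$eb)
  })
  expect_identical(op_s$criticality, "supercritical-stable")
  expect_lt(op_s$psi_L, op_s$psi_crit)
  expect_lt(abs(op_s$mismatch), 1e-9)
  # brute-force check: supply minus demand really has no subcritical
  # root and a falling-branch intersection
  ctl <- stomopt:::coupler_control()
  ps_sub <- seq(-0.705, op_s$psi_crit, length.out = 15)
  G_sub <- stomopt:::supply_minus_demand(ps_sub, -0.7, env, fx$photo,
                                         fx$pv, hyd_mid, fx$eb, ctl)
  expect_true(all(G_sub < 0))
  expect_equal(stomopt:::supply_minus_demand(op_s$psi_L, -0.7, env,
                                             fx$photo, fx$pv, hyd_mid,
                                             fx$eb, ctl), 0,
               tolerance = 1e-7)
})

test_that("warm-started solves agree with cold solves", {
  env <- leaf_environment(T_air = 301.15, RH = 0.45)
  cold <- solve_operating_point(-0.6, env, fx$photo, fx$pv, fx$hyd, fx$eb)
  warm <- solve_operating_point(-0.6, env, fx$photo, fx$pv, fx$hyd, fx$eb,
                                warm = list(psi_L = cold$psi_L - 0.05,
                                            T_L = cold$T_L))
  expect_equal(warm$psi_L, cold$psi_L, tolerance = 1e-6)
  expect_identical(warm$criticality, cold$criticality)
})

test_that("the coupled temperature response peaks at intermediate temperature", {
  res <- temperature_sweep()
  peak <- res$Ta[which.max(res$gw)] - 273.15
  expect_gt(peak, 20); expect_lt(peak, 30)
  # declines beyond the optimum until extreme-heat closure
  hot <- res[res$Ta - 273.15 >= peak & res$Ta - 273.15 <= 42.5, ]
  expect_true(all(diff(hot$gw) < 0))
  # VPD closure when RH is varied at fixed air temperature, and the
  # coupled sensitivity exceeds the fixed-leaf-state sensitivity
  sweep_rh <- cached("rh_sweep", {
    warm <- NULL; out <- NULL
    for (rh in seq(0.85, 0.08, by = -0.055)) {
      env <- leaf_environment(T_air = 299.15, RH = rh)
      op <- solve_operating_point(-0.3, env, fx$photo, fx$pv, fx$hyd,
                                  fx$eb, warm = warm)
      warm <- list(psi_L = op$psi_L, T_L = op$T_L)
      out <- rbind(out, data.frame(D = op$D_L, gw = op$gas$gw))
    }
    out
  })
  expect_true(all(diff(sweep_rh$gw[order(sweep_rh$D)]) < 0))
  m_coupled <- vpd_sensitivity_m(sweep_rh$D, sweep_rh$gw)
  # fixed leaf state (hydration and temperature pinned)
  st <- state_from_psi(-0.3, 299.15, fx$pv)
  gw_fix <- vapply(sweep_rh$D, function(D) {
    optimal_gas_exchange(st, leaf_environment(D_L = D, T_air = 299.15),
                         fx$photo, fx$pv)$gw
  }, 0)
  m_fixed <- vpd_sensitivity_m(sweep_rh$D, gw_fix)
  expect_gt(m_coupled, m_fixed)
  expect_gt(m_coupled, 0)
})
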