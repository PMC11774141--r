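test_that("osmotic potential at full hydration scales with absolute temperature", {
  expect_equal(pi_L0_at_T(-1.5, 298.15), -1.5)
  expect_equal(pi_L0_at_T(-1.5, 308.15), -1.55031024652, tolerance = 1e-10)
  expect_equal(pi_L0_at_T(-2.0, 288.15), -1.93291967131, tolerance = 1e-10)
  expect_error(pi_L0_at_T(-1.5, 200), "range")
  expect_error(pi_L0_at_T(1.5, 298.15), "negative")
})

test_that("apoplastic fraction follows the Weibull response", {
  p <- leaf_pv_params(af_max = 0.3, pi_L_star = -3, beta = 2, eps_L0 = 10,
                      SWC_L = 2, alpha = 3, pi_L0_25 = -1.5)
  expect_equal(apoplastic_fraction(0, p), 0.3)
  expect_equal(apoplastic_fraction(-3, p), 0.3 * exp(-1))
  expect_equal(apoplastic_fraction(-1.5, p), 0.233640234921,
               tolerance = 1e-10)
  expect_error(apoplastic_fraction(0.1, p), "<= 0")
  # monotone decreasing with |pi_L|
  af <- apoplastic_fraction(seq(-0.1, -6, by = -0.1), p)
  expect_true(all(diff(af) < 0))
})

test_that("osmotic potential inverts total relative water content", {
  pv <- fx$pv
  pi0 <- pi_L0_at_T(pv$pi_L0_25, 298.15)
  expect_equal(osmotic_potential(1, 298.15, pv), pi0)
  # halved symplast at frozen apoplast doubles the concentration:
  # build a rigid-apoplast trait set (beta tiny keeps af ~ af_max)
  pr <- leaf_pv_params(af_max = 1e-6, pi_L_star = -3, beta = 2,
                       eps_L0 = 10, SWC_L = 2, alpha = 3, pi_L0_25 = -1.5)
  rwc_half <- 1e-6 + (1 - 1e-6) * 0.5
  expect_equal(osmotic_potential(rwc_half, 298.15, pr), 2 * (-1.5),
               tolerance = 1e-5)
  # grid-scan oracle at RWC = 0.9
  grid <- seq(pi0 * 20, pi0, length.out = 2e5)
  resid <- abs(stomopt:::rwc_from_pi(grid, 298.15, pv) - 0.9)
  pi_scan <- grid[which.min(resid)]
  pi_solved <- osmotic_potential(0.9, 298.15, pv)
  expect_equal(pi_solved, pi_scan, tolerance = 1e-3)
  # and the implicit equation is satisfied to solver tolerance
  af0 <- stomopt:::af0_at_T(pv, 298.15)
  lhs <- pi_solved * (0.9 - apoplastic_fraction(pi_solved, pv))
  expect_equal(lhs, pi0 * (1 - af0), tolerance = 1e-8)
  expect_error(osmotic_potential(1e-6, 298.15, pv), "infeasible")
})

test_that("turgor follows the linear elastic segment and clamps at zero", {
  pv <- fx$pv
  pi0 <- pi_L0_at_T(pv$pi_L0_25, 298.15)
  st <- state_from_psi(-1e-12, 298.15, pv)
  expect_equal(st$P_L, -pi0, tolerance = 1e-9)
  # direct evaluation on the linear segment: eps 12, pi_L0 -1.8,
  # RWC_s = 0.95 gives P = 1.8 + 12 * (-0.05) = 1.2
  p2 <- leaf_pv_params(af_max = 0.3, pi_L_star = -3, beta = 2,
                       eps_L0 = 12, SWC_L = 2, alpha = 3, pi_L0_25 = -1.8)
  af0 <- stomopt:::af0_at_T(p2, 298.15)
  pi_L <- -1.8 / 0.95           # RWC_s = pi_L0 / pi_L on the manifold
  rwc <- apoplastic_fraction(pi_L, p2) + 0.95 * (1 - af0)
  expect_equal(turgor(pi_L, rwc, 298.15, p2), 1.2, tolerance = 1e-9)
  # zero at the turgor-loss point by construction
  wp <- wilting_point(p2, 298.15)
  expect_equal(turgor(wp$pi_tlp, wp$RWC_tlp, 298.15, p2), 0)
})

test_that("wilting point matches a brute-force scan and its limits", {
  pv <- fx$pv
  wp <- wilting_point(pv, 298.15)
  # scan RWC downward for the first zero-turgor state
  rwc_grid <- seq(1, 0.3, by = -1e-4)
  pis <- osmotic_potential(rwc_grid, 298.15, pv)
  P <- turgor(pis, rwc_grid, 298.15, pv)
  first0 <- rwc_grid[which(P <= 0)[1]]
  expect_equal(wp$RWC_tlp, first0, tolerance = 6e-4)
  expect_lt(wp$psi_tlp, pi_L0_at_T(pv$pi_L0_25, 298.15))
  # rigid-cell limit: psi_tlp -> pi_L0
  stiff <- leaf_pv_params(0.3, -3, 2, eps_L0 = 5e4, SWC_L = 2, alpha = 3,
                          pi_L0_25 = -1.5)
  expect_equal(wilting_point(stiff, 298.15)$psi_tlp, -1.5,
               tolerance = 1e-4)
})

test_that("leaf state from water potential is the inverse of the forward map", {
  pv <- fx$pv
  expect_equal(state_from_psi(0, 298.15, pv)$RWC_LT, 1, tolerance = 1e-9)
  wp <- wilting_point(pv, 298.15)
  expect_equal(state_from_psi(wp$psi_tlp, 298.15, pv)$RWC_LT, wp$RWC_tlp,
               tolerance = 1e-9)
  expect_error(state_from_psi(wp$psi_tlp - 0.5, 298.15, pv), "infeasible")
  expect_error(state_from_psi(0.2, 298.15, pv), "infeasible")
  # round trip over a 50-point grid
  psis <- seq(wp$psi_tlp + 1e-9, -1e-9, length.out = 50)
  for (ps in psis) {
    st <- state_from_psi(ps, 298.15, pv)
    expect_equal(st$psi_L, ps, tolerance = 1e-8)
    expect_equal(osmotic_potential(st$RWC_LT, 298.15, pv), st$pi_L,
                 tolerance = 1e-8)
    expect_true(st$a_f < st$RWC_LT && st$RWC_LT <= 1 + 1e-12)
    expect_equal(st$psi_L, st$P_L + st$pi_L, tolerance = 1e-9)
  }
})

test_that("pi_L declines with dehydration and af declines with pi_L", {
  pv <- fx$pv
  rwc <- seq(1, 0.55, by = -0.01)
  pis <- osmotic_potential(rwc, 298.15, pv)
  expect_true(all(diff(pis) < 0))
  expect_true(all(diff(apoplastic_fraction(pis, pv)) < 0))
})

test_that("trait-set validation rejects unphysical combinations", {
  expect_error(leaf_pv_params(1.2, -3, 2, 10, 2, 3, -1.5), "af_max")
  expect_error(leaf_pv_params(0.3, 3, 2, 10, 2, 3, -1.5), "pi_L_star")
  expect_error(leaf_pv_params(0.3, -3, 2, 10, 2, 3, 1.5), "pi_L0_25")
  expect_error(leaf_pv_params(0.3, -3, -1, 10, 2, 3, -1.5), "beta")
})
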