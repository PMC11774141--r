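test_that("USO conductance solves the coupled Medlyn relation", {
  pat <- photo_at_T(fx$photo, 298.15, ref_env$PPFD)
  # decoupled check with an imposed assimilation rate
  ge <- uso_gw(leaf_environment(D_L = 1), pat, g1 = 3, An_imposed = 10e-6,
               g0 = 0)
  expect_equal(ge$gw, 1.6 * (1 + 3) * 10e-6 / 420e-6, tolerance = 1e-12)
  # self-consistency of the coupled solution
  ge2 <- uso_gw(ref_env, pat, g1 = 4)
  expect_equal(ge2$gw,
               1.6 * (1 + 4 / sqrt(ref_env$D_L)) * ge2$An / ref_env$ca,
               tolerance = 1e-8)
  # g1 -> 0 limit
  ge0 <- uso_gw(ref_env, pat, g1 = 0, g0 = 0.01)
  expect_equal(ge0$gw, 0.01 + 1.6 * ge0$An / ref_env$ca, tolerance = 1e-8)
  # monotone closure with VPD
  gws <- vapply(c(0.8, 1.5, 2.5, 3.5), function(D) {
    uso_gw(leaf_environment(D_L = D), pat, g1 = 4)$gw
  }, 0)
  expect_true(all(diff(gws) < 0))
})

test_that("g1 fitting recovers the generating slope and tracks the water price", {
  pat <- photo_at_T(fx$photo, 298.15, ref_env$PPFD)
  set.seed(5)
  n <- 60
  D <- runif(n, 0.6, 3.5)
  dat <- do.call(rbind, lapply(D, function(d) {
    ge <- uso_gw(leaf_environment(D_L = d), pat, g1 = 4)
    data.frame(gw_obs = ge$gw, An_obs = ge$An, D_L = d, ca = 420e-6,
               PPFD = ref_env$PPFD, Patm = 101.325, T_leaf = 298.15)
  }))
  g1_hat <- fit_g1(dat)
  expect_equal(as.numeric(g1_hat), 4, tolerance = 1e-4)
  # with noise at realistic n the slope is still recovered within 5%
  set.seed(6)
  dat_n <- dat[sample.int(n, 300, replace = TRUE), ]
  dat_n$gw_obs <- pmax(dat_n$gw_obs + rnorm(300, 0, 0.02), 1e-4)
  expect_lt(abs(as.numeric(fit_g1(dat_n)) - 4) / 4, 0.05)
  # datasets generated at increasing imposed water price fit smaller g1
  g1s <- vapply(c(1e-3, 2e-3, 4e-3), function(lam) {
    rows <- do.call(rbind, lapply(seq(0.8, 3.2, length.out = 15),
      function(d) {
        env <- leaf_environment(D_L = d)
        ge <- gw_from_lambda_closed(lam, env, pat)
        data.frame(gw_obs = ge$gw, An_obs = ge$An, D_L = d, ca = 420e-6,
                   PPFD = ref_env$PPFD, Patm = 101.325, T_leaf = 298.15)
      }))
    as.numeric(fit_g1(rows))
  }, 0)
  expect_true(all(diff(g1s) < 0))
})

test_that("the constant-price scheme matches the full model only at its own price", {
  pv <- fx$pv
  st <- state_from_psi(-0.4, 298.15, pv)
  pat <- photo_at_T(fx$photo, 298.15, ref_env$PPFD, psi_L = st$psi_L)
  chi <- chi_w_closed(st, pv)
  ge_cf <- cowan_farquhar_gw(chi, ref_env, pat)
  ge_opt <- optimal_gas_exchange(st, ref_env, fx$photo, pv)
  expect_equal(ge_cf$gw, ge_opt$gw, tolerance = 1e-9)
  # doubling the fixed price closes stomata
  expect_lt(cowan_farquhar_gw(2 * chi, ref_env, pat)$gw, ge_cf$gw)
  # the fixed-price scheme collapses at extreme heat with no reopening
  gw_hot <- vapply(seq(303.15, 325.15, by = 2.5), function(Ta) {
    e_air <- 0.5 * stomopt:::esat_kpa(Ta)
    env <- leaf_environment(T_air = Ta,
                            D_L = max(stomopt:::esat_kpa(Ta) - e_air,
                                      0.01))
    p <- photo_at_T(fx$photo, pmin(Ta, 332), env$PPFD, peaked = TRUE)
    cowan_farquhar_gw(chi, env, p)$gw
  }, 0)
  expect_true(all(diff(gw_hot) <= 1e-12))
  expect_equal(gw_hot[length(gw_hot)], 0.005)
})

test_that("the Gain-Risk optimizer balances carbon gain against conductance loss", {
  hyd <- fx$hyd
  pat <- photo_at_T(fx$photo, 298.15, ref_env$PPFD)
  ge <- gain_risk_gw(-0.1, ref_env, pat, hyd)
  psi_L <- attr(ge, "psi_L")
  # wet soil, low VPD: interior optimum well below critical
  expect_gt(ge$gw, 0.01)
  expect_gt(psi_L, critical_point(-0.1, 298.15, hyd)$psi_crit)
  expect_lt(attr(ge, "PLC"), plc(critical_point(-0.1, 298.15,
                                                hyd)$psi_crit, hyd))
  # numeric optimization oracle at the fixture point
  k_soil <- conductance(-0.1, 298.15, hyd)
  An_max <- {
    gw_crit <- critical_point(-0.1, 298.15, hyd)$E_crit * ref_env$Patm /
      ref_env$D_L
    cc <- stomopt:::ci_given_gw(gw_crit, ref_env$ca,
                                pat$carboxylation$f0,
                                pat$carboxylation$gamma, pat$Gamma_star,
                                pat$Rd)
    an_of_ci(cc, pat$carboxylation$f0, pat$carboxylation$gamma,
             pat$Gamma_star, pat$Rd)
  }
  obj <- function(gw) {
    E <- gw * ref_env$D_L / ref_env$Patm
    psi <- stomopt:::supply_inverse_subcritical(E, -0.1, 298.15, hyd)
    cc <- stomopt:::ci_given_gw(gw, ref_env$ca, pat$carboxylation$f0,
                                pat$carboxylation$gamma, pat$Gamma_star,
                                pat$Rd)
    ce <- stomopt:::ci_given_gw(gw, ref_env$ca,
                                pat$electron_transport$f0,
                                pat$electron_transport$gamma,
                                pat$Gamma_star, pat$Rd)
    An <- min(an_of_ci(cc, pat$carboxylation$f0, pat$carboxylation$gamma,
                       pat$Gamma_star, pat$Rd),
              an_of_ci(ce, pat$electron_transport$f0,
                       pat$electron_transport$gamma, pat$Gamma_star,
                       pat$Rd))
    An / An_max - (k_soil - conductance(psi, 298.15, hyd)) / k_soil
  }
  grid <- seq(0.005, critical_point(-0.1, 298.15, hyd)$E_crit *
                ref_env$Patm / ref_env$D_L, length.out = 4000)
  expect_equal(ge$gw, grid[which.max(vapply(grid, obj, 0))],
               tolerance = 1e-3)
  # pure-risk limit: with no gain the stomata sit on the floor
  pat0 <- pat
  pat0$carboxylation$f0 <- 1e-12
  pat0$electron_transport$f0 <- 1e-12
  expect_equal(gain_risk_gw(-0.1, ref_env, pat0, hyd)$gw, 0.005,
               tolerance = 1e-6)
  # never supercritical by construction
  for (ps in c(-0.2, -0.8, -1.5)) {
    g <- gain_risk_gw(ps, ref_env, pat, hyd)
    expect_gte(attr(g, "psi_L"), critical_point(ps, 298.15, hyd)$psi_crit)
  }
})

test_that("the scheme registry lists the four stomatal schemes", {
  expect_setequal(stomatal_schemes(), c("chi_w", "uso", "cowan",
                                        "gainrisk"))
})
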