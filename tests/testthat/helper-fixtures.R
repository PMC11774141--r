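# Shared fixtures and a per-session cache for the expensive simulation
# products reused across test files.

fx <- fixture_params()
ref_env <- leaf_environment()

.test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .test_cache, inherits = FALSE)) {
    assign(name, force(expr), envir = .test_cache)
  }
  get(name, envir = .test_cache, inherits = FALSE)
}

# random pressure-volume trait draws inside the calibration prior box
random_pv_draw <- function() {
  b <- default_prior_bounds()
  repeat {
    p <- tryCatch(
      leaf_pv_params(af_max = runif(1, b$af_max[1], b$af_max[2]),
                     pi_L_star = runif(1, b$pi_L_star[1], b$pi_L_star[2]),
                     beta = runif(1, b$beta[1], b$beta[2]),
                     eps_L0 = runif(1, b$eps_L0[1], b$eps_L0[2]),
                     SWC_L = runif(1, b$SWC_L[1], b$SWC_L[2]),
                     alpha = runif(1, b$alpha[1], b$alpha[2]),
                     pi_L0_25 = runif(1, b$pi_L0_25[1], b$pi_L0_25[2]),
                     c_DM = 500),
      error = function(e) NULL)
    if (!is.null(p)) return(p)
  }
}

# golden-section style optimization oracle: argmax over gw of
# An(gw) - lambda * E(gw) under the minimum-assimilation rule
gw_optimization_oracle <- function(lambda, env, pat, lower = 1e-6,
                                   upper = 2) {
  f <- function(gw) {
    cc <- stomopt:::ci_given_gw(gw, env$ca, pat$carboxylation$f0,
                                pat$carboxylation$gamma, pat$Gamma_star,
                                pat$Rd)
    ce <- stomopt:::ci_given_gw(gw, env$ca, pat$electron_transport$f0,
                                pat$electron_transport$gamma,
                                pat$Gamma_star, pat$Rd)
    An <- min(an_of_ci(cc, pat$carboxylation$f0, pat$carboxylation$gamma,
                       pat$Gamma_star, pat$Rd),
              an_of_ci(ce, pat$electron_transport$f0,
                       pat$electron_transport$gamma, pat$Gamma_star,
                       pat$Rd))
    An - lambda * gw * env$D_L / env$Patm
  }
  stats::optimize(f, c(lower, upper), maximum = TRUE, tol = 1e-10)$maximum
}
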