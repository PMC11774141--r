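#' Default prior bounds for the calibrated traits
#'
#' Uniform physiological ranges: six species-shared traits plus the
#' treatment-specific osmotic potential at full hydration.
#'
#' @return Named list of `c(lower, upper)` pairs.
#' @export
default_prior_bounds <- function() {
  list(af_max = c(0.05, 0.6), eps_L0 = c(5, 30), pi_L_star = c(-8, -0.5),
       beta = c(0.5, 6), SWC_L = c(1, 4), alpha = c(1, 30),
       pi_L0_25 = c(-3.5, -0.8))
}

#' Calibration configuration
#'
#' @param n_iter DE-MC generations.
#' @param burn_frac Fraction of generations discarded as burn-in.
#' @param seed RNG seed.
#' @param n_chains Chain count; defaults to `2 * d + 1` for `d` free
#'   parameters.
#' @param thin Keep every `thin`-th post-burn-in generation.
#' @param psrf_threshold Convergence threshold on the potential scale
#'   reduction factor.
#' @param closure_threshold Wilting-filter threshold: modelled gw at the
#'   wilting point may be at most this fraction of the full-hydration gw.
#' @param apply_filter Apply the wilting-closure filter inside the
#'   prior?
#' @param bounds Prior bounds, as from [default_prior_bounds()].
#' @param ref_env Reference environment for the wilting filter.
#' @param g0_min Conductance floor (mol m^-2 s^-1).
#' @return List of class `calib_config`.
#' @export
calib_config <- function(n_iter = 3000, burn_frac = 0.5, seed = 1,
                         n_chains = NULL, thin = 5, psrf_threshold = 1.2,
                         closure_threshold = 0.05, apply_filter = TRUE,
                         bounds = default_prior_bounds(),
                         ref_env = leaf_environment(), g0_min = 0.005) {
  structure(list(n_iter = n_iter, burn_frac = burn_frac, seed = seed,
                 n_chains = n_chains, thin = thin,
                 psrf_threshold = psrf_threshold,
                 closure_threshold = closure_threshold,
                 apply_filter = apply_filter, bounds = bounds,
                 ref_env = ref_env, g0_min = g0_min),
            class = "calib_config")
}

# Parameter vector <-> pv params.  theta is a named vector with the six
# shared traits plus one pi_L0_25.<treatment> entry per treatment.
theta_names <- function(treatments) {
  c("af_max", "eps_L0", "pi_L_star", "beta", "SWC_L", "alpha",
    paste0("pi_L0_25.", treatments))
}

theta_to_pv <- function(theta, treatment, constants = physical_constants(),
                        c_DM = 500) {
  leaf_pv_params(af_max = theta[["af_max"]],
                 pi_L_star = theta[["pi_L_star"]],
                 beta = theta[["beta"]], eps_L0 = theta[["eps_L0"]],
                 SWC_L = theta[["SWC_L"]], alpha = theta[["alpha"]],
                 pi_L0_25 = theta[[paste0("pi_L0_25.", treatment)]],
                 c_DM = c_DM, constants = constants)
}

theta_bounds_matrix <- function(treatments, bounds = default_prior_bounds()) {
  nm <- theta_names(treatments)
  lower <- c(bounds$af_max[1], bounds$eps_L0[1], bounds$pi_L_star[1],
             bounds$beta[1], bounds$SWC_L[1], bounds$alpha[1],
             rep(bounds$pi_L0_25[1], length(treatments)))
  upper <- c(bounds$af_max[2], bounds$eps_L0[2], bounds$pi_L_star[2],
             bounds$beta[2], bounds$SWC_L[2], bounds$alpha[2],
             rep(bounds$pi_L0_25[2], length(treatments)))
  matrix(c(lower, upper), ncol = 2,
         dimnames = list(nm, c("lower", "upper")))
}

# Continuous closure score: the worst (largest) ratio of modelled gw at
# the wilting point to modelled gw at full hydration across treatments.
closure_ratio <- function(theta, photo, config = calib_config()) {
  trs <- sub("^pi_L0_25\\.", "",
             grep("^pi_L0_25\\.", names(theta), value = TRUE))
  env <- config$ref_env
  worst <- 0
  for (tr in trs) {
    pv <- tryCatch(theta_to_pv(theta, tr), error = function(e) NULL)
    if (is.null(pv)) return(Inf)
    if (pv$eps_L0 + pi_L0_at_T(pv$pi_L0_25, env$T_air) <= 0) return(Inf)
    wp <- wilting_point(pv, env$T_air)
    d <- data.frame(treatment = tr, psi_L = c(-1e-9, wp$psi_tlp),
                    T_leaf = env$T_air, D_L = env$D_L, ca = env$ca,
                    PPFD = env$PPFD, Patm = env$Patm)
    gw <- predict_gw_table(d, stats::setNames(list(pv), tr), photo,
                           g0_min = config$g0_min)$gw
    worst <- max(worst, gw[2] / gw[1])
  }
  worst
}

#' Wilting-point closure filter
#'
#' A trait combination is physiologically admissible only if it drives
#' near-complete stomatal closure at the leaf wilting point: the
#' modelled conductance at the turgor-loss point must not exceed a set
#' fraction (default 5%, inclusive) of the modelled conductance at full
#' hydration under a reference environment.
#'
#' @param theta Named parameter vector (see [run_mcmc()]).
#' @param photo A [photo_params()] object.
#' @param config A [calib_config()].
#' @return `TRUE` if every treatment's trait set passes.
#' @export
wilting_closure_filter <- function(theta, photo, config = calib_config()) {
  closure_ratio(theta, photo, config) <= config$closure_threshold
}

#' Gaussian log-likelihood of observed stomatal conductance
#'
#' Model conductances are driven by each row's observed leaf water
#' potential, leaf temperature and environment; residuals are iid
#' Gaussian with the noise variance profiled at its conditional MLE.
#' Rows where the model is infeasible predict the cuticular floor and
#' are counted in the `n_infeasible` attribute.
#'
#' @param theta Named parameter vector.
#' @param data Observation table (see [generate_gas_exchange()]).
#' @param photo A [photo_params()] object.
#' @param g0_min Conductance floor (mol m^-2 s^-1).
#' @return Log-likelihood (scalar) with attributes `sigma_hat` and
#'   `n_infeasible`.
#' @export
log_likelihood <- function(theta, data, photo, g0_min = 0.005,
                           censored = TRUE) {
  if (nrow(data) == 0) {
    return(structure(0, sigma_hat = NA_real_, n_infeasible = 0L))
  }
  trs <- unique(data$treatment)
  pv_by <- tryCatch(
    stats::setNames(lapply(trs, function(tr) theta_to_pv(theta, tr)), trs),
    error = function(e) NULL)
  if (is.null(pv_by)) return(structure(-Inf, sigma_hat = NA_real_,
                                       n_infeasible = nrow(data)))
  pred <- predict_gw_table(data, pv_by, photo, g0_min = g0_min)
  resid <- data$gw_obs - pred$gw
  n <- length(resid)
  cens <- censored & data$gw_obs <= g0_min + 1e-12
  if (any(cens)) {
    # observations sitting exactly on the cuticular floor are
    # left-censored (the recording floor truncates the noise); the
    # noise SD is profiled numerically
    r_open <- resid[!cens]
    z_cens <- g0_min - pred$gw[cens]
    nll <- function(log_s) {
      s <- exp(log_s)
      -(sum(stats::dnorm(r_open, 0, s, log = TRUE)) +
          sum(stats::pnorm(z_cens / s, log.p = TRUE)))
    }
    opt <- stats::optimize(nll, c(log(1e-4), log(0.5)), tol = 1e-10)
    ll <- -opt$objective
    s_hat <- exp(opt$minimum)
  } else {
    s2 <- max(mean(resid^2), 1e-12)
    ll <- -0.5 * n * (log(2 * pi * s2) + 1)
    s_hat <- sqrt(s2)
  }
  structure(ll, sigma_hat = s_hat, n_infeasible = sum(!pred$feasible))
}

log_prior <- function(theta, bmat, photo, config) {
  if (any(theta < bmat[, "lower"]) || any(theta > bmat[, "upper"])) {
    return(-Inf)
  }
  if (config$apply_filter &&
      !wilting_closure_filter(theta, photo, config)) {
    return(-Inf)
  }
  0
}

#' Differential-evolution MCMC over the hierarchical trait vector
#'
#' Calibrates the six species-shared traits and one treatment-specific
#' osmotic potential at full hydration per treatment against observed
#' stomatal conductances, with uniform priors, the wilting-closure
#' filter, and a ter Braak-style differential-evolution proposal
#' (`gamma = 2.38 / sqrt(2 d)`, a unit-gamma mode-jumping generation
#' every tenth step, and a small uniform jitter).  Deterministic given
#' the configuration seed.
#'
#' @param data Observation table; its `treatment` column defines the
#'   hierarchy.  May have zero rows (prior-only run).
#' @param config A [calib_config()].
#' @param photo A [photo_params()] object.
#' @param treatments Treatment labels; defaults to those present in
#'   `data`.
#' @return Object of class `mcmc_fit`: list with `samples` (data frame
#'   of post-burn-in draws with their log-posteriors), `acceptance`,
#'   `psrf` (per-parameter potential scale reduction), `converged`,
#'   `config`.
#' @export
run_mcmc <- function(data, config = calib_config(),
                     photo = fixture_params()$photo,
                     treatments = NULL) {
  treatments <- treatments %||% unique(data$treatment)
  if (!length(treatments)) treatments <- "control"
  bmat <- theta_bounds_matrix(treatments, config$bounds)
  d <- nrow(bmat)
  n_chains <- config$n_chains %||% (2L * d + 1L)
  if (n_chains < 2 * d + 1) stop("need at least 2*d + 1 chains")
  logpost <- function(theta) {
    lp <- log_prior(theta, bmat, photo, config)
    if (!is.finite(lp)) return(-Inf)
    lp + as.numeric(log_likelihood(theta, data, photo,
                                   g0_min = config$g0_min))
  }
  with_seed(config$seed, {
    # Initialize chains inside the admissible region.  The
    # wilting-closure filter admits only a thin wedge of the prior box,
    # so plain rejection sampling is hopeless; instead, for each random
    # draw of the other traits the osmolyte size alpha is scanned (the
    # marginal cost scales linearly in alpha), which locates admissible
    # combinations cheaply.  Used for initialization only; the sampler
    # itself explores the filtered posterior.
    X <- matrix(NA_real_, n_chains, d, dimnames = list(NULL, rownames(bmat)))
    lp <- numeric(n_chains)
    alpha_grid <- exp(seq(log(bmat["alpha", 1] + 1e-6),
                          log(bmat["alpha", 2] - 1e-6), length.out = 14))
    found <- 0L
    for (try in seq_len(12000L)) {
      cand <- stats::runif(d, bmat[, 1], bmat[, 2])
      names(cand) <- rownames(bmat)
      if (!config$apply_filter) {
        v <- logpost(cand)
        if (!is.finite(v)) next
        found <- found + 1L
        X[found, ] <- cand; lp[found] <- v
      } else {
        # cheap pre-screen: the wilting/full-hydration marginal-cost
        # ratio must be large for any alpha to achieve closure
        pre_ok <- TRUE
        for (tr in treatments) {
          pv <- tryCatch(theta_to_pv(cand, tr), error = function(e) NULL)
          if (is.null(pv) ||
              pv$eps_L0 + pi_L0_at_T(pv$pi_L0_25, 298.15) <= 0) {
            pre_ok <- FALSE; break
          }
          wp <- wilting_point(pv, 298.15)
          c_full <- chi_w_closed(state_from_psi(-1e-9, 298.15, pv), pv,
                                 strict = FALSE)
          c_tlp <- chi_w_closed(state_from_psi_any(wp$psi_tlp, 298.15, pv),
                                pv, strict = FALSE)
          if (c_full <= 0 || c_tlp / c_full < 2.5) { pre_ok <- FALSE; break }
        }
        if (!pre_ok) next
        hit <- FALSE
        for (a in alpha_grid) {
          cand[["alpha"]] <- a
          if (closure_ratio(cand, photo, config) <=
                config$closure_threshold) { hit <- TRUE; break }
        }
        if (!hit) next
        v <- logpost(cand)
        if (!is.finite(v)) next
        found <- found + 1L
        X[found, ] <- cand; lp[found] <- v
      }
      if (found >= n_chains) break
    }
    if (found == 0L) {
      stop("could not initialize MCMC: the prior+filter admits too ",
           "few trait combinations")
    }
    # top up the chain set by jittering located admissible points
    guard <- 0L
    while (found < n_chains && guard < 20000L) {
      guard <- guard + 1L
      base <- X[sample.int(found, 1L), ]
      cand <- base + stats::rnorm(d, 0, 0.03) * (bmat[, 2] - bmat[, 1])
      cand <- pmin(pmax(cand, bmat[, 1]), bmat[, 2])
      names(cand) <- rownames(bmat)
      v <- logpost(cand)
      if (!is.finite(v)) next
      found <- found + 1L
      X[found, ] <- cand; lp[found] <- v
    }
    if (found < n_chains) {
      stop("could not initialize MCMC: failed to assemble a full ",
           "admissible chain set")
    }
    # sharpen the start: refine the best admissible point toward the
    # posterior mode (bounded Nelder-Mead on the penalized logpost) and
    # seed half of the chains near it; the rest keep the dispersed
    # admissible cloud so the split-chain PSRF remains meaningful
    if (nrow(data) > 0) {
      # soft-penalized objective for the mode search: the closure
      # filter is a razor-thin wedge, so its indicator is replaced by a
      # smooth penalty on the continuous closure ratio (plus a bounds
      # penalty); the refined point is only used if it passes the
      # actual filter
      pen <- function(theta) {
        names(theta) <- rownames(bmat)
        out_lo <- pmax(bmat[, 1] - theta, 0)
        out_hi <- pmax(theta - bmat[, 2], 0)
        bpen <- 1e8 * sum((out_lo + out_hi)^2)
        th <- pmin(pmax(theta, bmat[, 1]), bmat[, 2])
        names(th) <- rownames(bmat)
        ll <- as.numeric(log_likelihood(th, data, photo,
                                        g0_min = config$g0_min))
        if (!is.finite(ll)) return(1e10)
        fpen <- if (config$apply_filter) {
          r <- closure_ratio(th, photo, config)
          if (!is.finite(r)) return(1e10)
          1e6 * max(0, r - config$closure_threshold)^2 +
            1e2 * max(0, r - config$closure_threshold)
        } else 0
        -ll + bpen + fpen
      }
      starts <- order(lp, decreasing = TRUE)[seq_len(min(3L, found))]
      best_val <- Inf; best_par <- NULL
      for (s in starts) {
        par <- X[s, ]
        for (round in 1:2) {
          opt <- stats::optim(par, pen, method = "Nelder-Mead",
                              control = list(maxit = 900,
                                             reltol = 1e-12))
          par <- opt$par
        }
        if (opt$value < best_val) { best_val <- opt$value
                                    best_par <- opt$par }
      }
      mode_pt <- pmin(pmax(best_par, bmat[, 1]), bmat[, 2])
      names(mode_pt) <- rownames(bmat)
      mode_lp <- logpost(mode_pt)
      if (!is.finite(mode_lp)) {
        # project back into the admissible wedge along alpha
        base_pt <- mode_pt
        for (a in sort(c(alpha_grid, base_pt[["alpha"]]))) {
          cand <- base_pt; cand[["alpha"]] <- a
          v <- logpost(cand)
          if (is.finite(v) && (!is.finite(mode_lp) || v > mode_lp)) {
            mode_pt <- cand; mode_lp <- v
          }
        }
      }
      if (is.finite(mode_lp) && mode_lp > max(lp)) {
        n_near <- (2L * n_chains) %/% 3L
        for (i in seq_len(n_near)) {
          for (k in seq_len(200L)) {
            cand <- mode_pt + stats::rnorm(d, 0, 0.01) *
              (bmat[, 2] - bmat[, 1])
            cand <- pmin(pmax(cand, bmat[, 1]), bmat[, 2])
            names(cand) <- rownames(bmat)
            v <- logpost(cand)
            if (is.finite(v)) { X[i, ] <- cand; lp[i] <- v; break }
          }
        }
      }
    }
    gamma0 <- 2.38 / sqrt(2 * d)
    span <- bmat[, 2] - bmat[, 1]
    n_keep <- 0L
    burn <- ceiling(config$n_iter * config$burn_frac)
    keep_gens <- seq(burn + 1L, config$n_iter)
    keep_gens <- keep_gens[keep_gens %% config$thin == 0]
    samples <- matrix(NA_real_, length(keep_gens) * n_chains, d,
                      dimnames = list(NULL, rownames(bmat)))
    lps <- numeric(length(keep_gens) * n_chains)
    chain_id <- integer(length(keep_gens) * n_chains)
    gen_id <- integer(length(keep_gens) * n_chains)
    accept <- 0L; total <- 0L
    for (g in seq_len(config$n_iter)) {
      # scaled differential proposals with occasional unit-gamma
      # mode-jumping generations
      gam <- if (g %% 10L == 0L) 1 else gamma0 * stats::runif(1, 0.3, 1)
      for (i in seq_len(n_chains)) {
        rs <- sample(setdiff(seq_len(n_chains), i), 2L)
        prop <- X[i, ] + gam * (X[rs[1], ] - X[rs[2], ]) +
          stats::runif(d, -1e-6, 1e-6) * span
        names(prop) <- rownames(bmat)
        lp_prop <- logpost(prop)
        total <- total + 1L
        if (is.finite(lp_prop) &&
            log(stats::runif(1)) < lp_prop - lp[i]) {
          X[i, ] <- prop; lp[i] <- lp_prop; accept <- accept + 1L
        }
      }
      if (g %in% keep_gens) {
        idx <- n_keep * n_chains + seq_len(n_chains)
        samples[idx, ] <- X
        lps[idx] <- lp
        chain_id[idx] <- seq_len(n_chains)
        gen_id[idx] <- g
        n_keep <- n_keep + 1L
      }
    }
    psrf <- vapply(seq_len(d), function(j) {
      gelman_rubin(samples[, j], chain_id)
    }, 0)
    names(psrf) <- rownames(bmat)
    out <- data.frame(samples, check.names = FALSE)
    out$log_posterior <- lps
    out$chain <- chain_id
    out$generation <- gen_id
    structure(list(samples = out, acceptance = accept / total,
                   psrf = psrf,
                   converged = all(psrf < config$psrf_threshold,
                                   na.rm = TRUE),
                   treatments = treatments, config = config),
              class = "mcmc_fit")
  })
}

# Split-chain potential scale reduction factor.
gelman_rubin <- function(x, chain_id) {
  chains <- split(x, chain_id)
  chains <- chains[vapply(chains, length, 0L) >= 4]
  if (length(chains) < 2) return(NA_real_)
  halves <- unlist(lapply(chains, function(v) {
    h <- length(v) %/% 2
    list(v[seq_len(h)], v[(h + 1):(2 * h)])
  }), recursive = FALSE)
  m <- length(halves); n <- min(vapply(halves, length, 0L))
  mat <- vapply(halves, function(v) v[seq_len(n)], numeric(n))
  mu <- colMeans(mat)
  B <- n * stats::var(mu)
  W <- mean(apply(mat, 2, stats::var))
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
print.mcmc_fit <- function(x, ...) {
  cat(sprintf("DE-MC fit: %d kept draws, acceptance %.2f, %s\n",
              nrow(x$samples), x$acceptance,
              if (isTRUE(x$converged)) "converged"
              else "NOT converged (PSRF above threshold)"))
  print(round(x$psrf, 3))
  invisible(x)
}

#' Posterior summary and goodness of fit
#'
#' Posterior medians and 95% intervals per parameter, predictive RMSE
#' and r-squared at the posterior-mode draw, and the contrasts between
#' treatment-level osmotic potentials.  `r2 = 1 - RSS / TSS` and may be
#' negative for a predictor worse than the observed mean.
#'
#' @param fit An `mcmc_fit`.
#' @param data Observation table to score (e.g. held-out rows).
#' @param photo A [photo_params()] object.
#' @return List with `summary` (data frame), `rmse`, `r2`, `theta_map`,
#'   `contrasts`.
#' @export
fit_report <- function(fit, data, photo = fixture_params()$photo) {
  pn <- rownames(theta_bounds_matrix(fit$treatments, fit$config$bounds))
  S <- as.matrix(fit$samples[, pn, drop = FALSE])
  summ <- data.frame(
    parameter = pn,
    median = apply(S, 2, stats::median),
    q025 = apply(S, 2, stats::quantile, 0.025),
    q975 = apply(S, 2, stats::quantile, 0.975),
    psrf = fit$psrf[pn], row.names = NULL)
  map_idx <- which.max(fit$samples$log_posterior)
  theta_map <- stats::setNames(as.numeric(S[map_idx, ]), pn)
  pv_by <- stats::setNames(
    lapply(fit$treatments, function(tr) theta_to_pv(theta_map, tr)),
    fit$treatments)
  pred <- predict_gw_table(data, pv_by, photo,
                           g0_min = fit$config$g0_min)
  resid <- data$gw_obs - pred$gw
  rmse <- sqrt(mean(resid^2))
  tss <- sum((data$gw_obs - mean(data$gw_obs))^2)
  r2 <- 1 - sum(resid^2) / tss
  pi_cols <- grep("^pi_L0_25\\.", pn, value = TRUE)
  contrasts <- if (length(pi_cols) > 1) {
    utils::combn(pi_cols, 2, function(pair) {
      diff <- S[, pair[1]] - S[, pair[2]]
      data.frame(contrast = paste(pair, collapse = " - "),
                 median = stats::median(diff),
                 q025 = stats::quantile(diff, 0.025),
                 q975 = stats::quantile(diff, 0.975))
    }, simplify = FALSE)
  } else {
    list()
  }
  list(summary = summ, rmse = rmse, r2 = r2, theta_map = theta_map,
       contrasts = if (length(contrasts)) do.call(rbind, contrasts)
                   else NULL)
}
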