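#' Osmotic potential at full hydration, scaled to leaf temperature
#'
#' The osmotic potential at full hydration is proportional to absolute
#' temperature under van't Hoff behaviour, so the trait is stored at the
#' 25 degC reference and rescaled to the current leaf temperature.
#'
#' @param pi_L0_25 Osmotic potential at full hydration at 25 degC
#'   (MPa, < 0).
#' @param T_LK Leaf temperature (K), within \[250, 340\].
#' @return Osmotic potential at full hydration at `T_LK` (MPa, < 0).
#' @export
pi_L0_at_T <- function(pi_L0_25, T_LK) {
  if (any(T_LK < 250 | T_LK > 340)) {
    stop("T_LK outside the supported range [250, 340] K")
  }
  if (any(pi_L0_25 >= 0)) stop("pi_L0_25 must be negative")
  pi_L0_25 * T_LK / 298.15
}

#' Apoplastic fraction as a Weibull function of osmotic potential
#'
#' `af = af_max * exp(-(pi_L / pi_L_star)^beta)`.  Both potentials are
#' negative, so the ratio is a positive real and the fraction declines
#' from `af_max` at `pi_L = 0` as the symplast concentrates.
#'
#' @param pi_L Symplastic osmotic potential (MPa, <= 0).
#' @param params A [leaf_pv_params()] object.
#' @return Apoplastic fraction (m^3 m^-3, fraction of the saturated leaf
#'   water volume).
#' @export
apoplastic_fraction <- function(pi_L, params) {
  if (any(pi_L > 0)) stop("pi_L must be <= 0")
  params$af_max * exp(-(pi_L / params$pi_L_star)^params$beta)
}

# Apoplastic fraction at full hydration at leaf temperature T.
af0_at_T <- function(params, T_LK) {
  apoplastic_fraction(pi_L0_at_T(params$pi_L0_25, T_LK), params)
}

# Total relative water content on the solute-conservation manifold as a
# closed function of pi_L: the symplastic water volume scales as
# pi_L0 * (1 - af_0) / pi_L and the apoplast follows the Weibull.
rwc_from_pi <- function(pi_L, T_LK, params) {
  pi_L0 <- pi_L0_at_T(params$pi_L0_25, T_LK)
  af0 <- af0_at_T(params, T_LK)
  apoplastic_fraction(pi_L, params) + pi_L0 * (1 - af0) / pi_L
}

#' Symplastic osmotic potential from total relative water content
#'
#' Solves the solute-conservation relation
#' `pi_L * (RWC_LT - af(pi_L)) = pi_L0(T) * (1 - af_0)` for `pi_L` by
#' bracketed bisection over `[1e3 * pi_L0, pi_L0]` (absolute tolerance
#' 1e-10 MPa).  At full hydration the solution is `pi_L0(T)` exactly.
#'
#' @param RWC_LT Total relative water content (fraction of saturated
#'   leaf water volume), in (0, 1].
#' @inheritParams pi_L0_at_T
#' @param params A [leaf_pv_params()] object.
#' @return Osmotic potential (MPa, < 0).
#' @export
osmotic_potential <- function(RWC_LT, T_LK, params) {
  if (any(RWC_LT > 1 + 1e-12)) stop("RWC_LT must be <= 1")
  pi_L0 <- pi_L0_at_T(params$pi_L0_25, T_LK)
  lo <- rep_len(pi_L0 * 1e3, length(RWC_LT))
  hi <- rep_len(pi_L0, length(RWC_LT))
  rwc_lo <- rwc_from_pi(lo, T_LK, params)
  if (any(RWC_LT <= rwc_lo)) {
    stop("infeasible leaf state: RWC_LT at or below the residual ",
         "apoplastic water content")
  }
  f <- function(p) rwc_from_pi(p, T_LK, params) - RWC_LT
  # bisection to 1e-10 MPa over a bracket of width |pi_L0| * 999
  iters <- ceiling(log2(abs(pi_L0[1]) * 999 / 1e-10)) + 2L
  res <- bisect_vec(f, lo, hi, iters = iters)
  ifelse(abs(RWC_LT - 1) <= 1e-12, pi_L0, res)
}

#' Turgor pressure from the linear-elastic pressure-volume segment
#'
#' `P = max(0, -pi_L0(T) + eps_L0 * (RWC_s - 1))`, with the symplastic
#' relative water content `RWC_s = (RWC_LT - af) / (1 - af_0)`.  Turgor
#' equals `-pi_L0` at full hydration and is clamped at zero at and below
#' the turgor-loss point.
#'
#' @inheritParams apoplastic_fraction
#' @inheritParams osmotic_potential
#' @return Turgor pressure (MPa, >= 0).
#' @export
turgor <- function(pi_L, RWC_LT, T_LK, params) {
  pi_L0 <- pi_L0_at_T(params$pi_L0_25, T_LK)
  af0 <- af0_at_T(params, T_LK)
  af <- apoplastic_fraction(pi_L, params)
  RWC_s <- (RWC_LT - af) / (1 - af0)
  pmax(0, -pi_L0 + params$eps_L0 * (RWC_s - 1))
}

#' Leaf wilting (turgor-loss) point
#'
#' For linear elasticity the turgor-loss point has a closed form: turgor
#' first reaches zero where the symplastic relative water content equals
#' `1 + pi_L0 / eps_L0`, i.e. at
#' `pi_tlp = pi_L0 * eps_L0 / (eps_L0 + pi_L0)`, and the total water
#' potential there equals the osmotic potential.
#'
#' @param params A [leaf_pv_params()] object.
#' @param T_LK Leaf temperature (K).
#' @return A list with elements `RWC_tlp`, `psi_tlp` and `pi_tlp`.
#' @export
wilting_point <- function(params, T_LK = 298.15) {
  pi_L0 <- pi_L0_at_T(params$pi_L0_25, T_LK)
  if (params$eps_L0 + pi_L0 <= 0) {
    stop("eps_L0 must exceed |pi_L0| for a turgor-loss point to exist")
  }
  pi_tlp <- pi_L0 * params$eps_L0 / (params$eps_L0 + pi_L0)
  list(RWC_tlp = rwc_from_pi(pi_tlp, T_LK, params),
       psi_tlp = pi_tlp, pi_tlp = pi_tlp)
}

# Assemble a validated leaf state from its osmotic potential (on the
# solute-conservation manifold).
leaf_state_from_pi <- function(pi_L, T_LK, params) {
  af <- apoplastic_fraction(pi_L, params)
  RWC <- rwc_from_pi(pi_L, T_LK, params)
  P <- turgor(pi_L, RWC, T_LK, params)
  structure(list(RWC_LT = RWC, T_LK = T_LK, pi_L = pi_L, a_f = af,
                 P_L = P, psi_L = P + pi_L),
            class = "leaf_state")
}

#' @export
print.leaf_state <- function(x, ...) {
  cat(sprintf(
    "Leaf state: RWC_LT %.4f  T %.2f K  pi_L %.4f  P %.4f  psi_L %.4f MPa\n",
    x$RWC_LT, x$T_LK, x$pi_L, x$P_L, x$psi_L))
  invisible(x)
}

# pi_L from total water potential, closed form.  On the turgid branch
# psi(pi_L) is a quadratic in pi_L; below the turgor-loss point
# psi == pi_L identically.  `extend = TRUE` admits post-turgor-loss
# (supercritical) states, which the whole-plant coupler requires.
pi_from_psi <- function(psi_L, T_LK, params, extend = FALSE) {
  pi_L0 <- pi_L0_at_T(params$pi_L0_25, T_LK)
  pi_tlp <- pi_L0 * params$eps_L0 / (params$eps_L0 + pi_L0)
  if (!extend && any(psi_L < pi_tlp - 1e-9 | psi_L > 1e-12)) {
    stop("infeasible leaf state: psi_L outside [psi_tlp, 0]")
  }
  b <- psi_L + pi_L0 + params$eps_L0
  disc <- b^2 - 4 * params$eps_L0 * pi_L0
  out <- 0.5 * (b - sqrt(pmax(disc, 0)))
  n <- max(length(psi_L), length(out), length(pi_tlp))
  out <- rep_len(out, n)
  psi_L <- rep_len(psi_L, n)
  pt <- rep_len(pi_tlp, n)
  sel <- psi_L <= pt
  if (any(sel)) out[sel] <- pmin(psi_L, pt)[sel]
  out
}

#' Leaf state from an observed total water potential
#'
#' Inverts the pressure-volume relations to recover the full leaf state
#' (relative water content, osmotic potential, apoplastic fraction,
#' turgor) driven by a measured leaf water potential.
#'
#' @param psi_L Total leaf water potential (MPa), in `[psi_tlp, 0]`.
#' @inheritParams osmotic_potential
#' @return A `leaf_state` object.
#' @export
state_from_psi <- function(psi_L, T_LK, params) {
  pi_L <- pi_from_psi(psi_L, T_LK, params, extend = FALSE)
  leaf_state_from_pi(pi_L, T_LK, params)
}

# Coupler-internal variant admitting supercritical (post-turgor-loss)
# water potentials.
state_from_psi_any <- function(psi_L, T_LK, params) {
  pi_L <- pi_from_psi(psi_L, T_LK, params, extend = TRUE)
  leaf_state_from_pi(pi_L, T_LK, params)
}
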