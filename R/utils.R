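# Internal numerical helpers.  All are vectorized and deterministic.

# Vectorized bisection for monotone scalar equations.  f must accept a
# vector and return a vector of the same length; lo/hi are vectors
# bracketing each root.  Runs a fixed iteration count so the whole
# calibration likelihood stays branch-free.
bisect_vec <- function(f, lo, hi, iters = 60L) {
  flo <- f(lo)
  for (i in seq_len(iters)) {
    mid <- 0.5 * (lo + hi)
    fm <- f(mid)
    take_lo <- (flo * fm) <= 0
    hi <- ifelse(take_lo, mid, hi)
    keep <- !take_lo
    lo <- ifelse(keep, mid, lo)
    flo <- ifelse(keep, fm, flo)
  }
  0.5 * (lo + hi)
}

# Saturation vapour pressure (kPa) over water, Tetens form; T in K.
esat_kpa <- function(T_K) {
  Tc <- T_K - 273.15
  0.61078 * exp(17.27 * Tc / (Tc + 237.3))
}

# Leaf-to-air vapour pressure deficit (kPa) from leaf temperature and
# ambient vapour pressure; floored to keep E > 0 well-defined.
vpd_leaf_kpa <- function(T_leaf_K, e_air_kpa, floor = 0.01) {
  pmax(esat_kpa(T_leaf_K) - e_air_kpa, floor)
}

# Arrhenius temperature scaling from the 25 degC reference.
arrhenius <- function(k25, Ea, T_K, R = 8.314, T_ref = 298.15) {
  k25 * exp(Ea * (T_K - T_ref) / (T_ref * R * T_K))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
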