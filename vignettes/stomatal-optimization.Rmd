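---
title: "Stomatal optimization from non-steady-state leaf storage: the model behind stomopt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stomatal optimization from non-steady-state leaf storage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stomopt)
```

# The model

`stomopt` implements a stomatal optimality scheme in which the marginal
carbon cost of water is not an empirical slope but a quantity derived
from the non-steady-state physics of what a leaf stores: water, solutes
and heat.  The reasoning is that stomatal opening immediately changes
only the *rates of change* of the leaf's own reserves — net assimilation
$A_n$ adds osmolytes to the mesophyll symplast, transpiration $E$
removes water (concentrating those solutes) and removes latent heat
(cooling the leaf, which scales the osmotic potential toward zero since
$\pi_L \propto T$).  Treating the mesophyll osmotic potential $\pi_L$ as
the single leaf-level constraint on a dynamic optimization of any
water-and-carbon-dependent fitness proxy collapses the problem to an
instantaneous rule: operate where the marginal carbon profit of water,

$$\lambda \;=\; \frac{\partial A_n/\partial g_w}{\partial E/\partial g_w},$$

equals the marginal carbon cost of water,

$$\chi_w \;=\; -\,\frac{\partial \dot\pi_L/\partial E}
                      {\partial \dot\pi_L/\partial A_n}.$$

## The mechanistic definition of the cost

`pi_dot()` assembles $\dot\pi_L$ from van't Hoff solute conservation
with a variable apoplast.  With $V_s$ the symplastic water volume,
$n_s$ the symplastic osmolyte amount and $T$ the leaf temperature,

$$\pi_L \,(RWC_{LT} - a_f(\pi_L))\,V_{sat} \;=\; -\varpi R T n_s ,$$

and the three flux channels are $\dot n_s = A_n/\alpha$ (one osmolyte
per $\alpha$ carbon atoms fixed), $\dot{RWC}_{LT} = -E\,m_w/(\rho_w
V_{sat})$, and $\dot T = -\Lambda_E m_w E / C_{heat}$ with the areal
heat capacity $C_{heat} = (SWC_L\,RWC_{LT}\,c_w + c_{DM})\,M_{DM}$.
`chi_w_numeric()` differentiates this model by central finite
differences; because $\dot\pi_L$ is linear in both fluxes the ratio is
independent of the linearization point and of the step (asserted by the
tests).  This finite-difference construction is the package's normative
definition of the cost.

## The closed form

Carrying the substitutions through by hand gives

$$\chi_w \;=\; \frac{\pi_{L,0}(T)\,(1-a_{f,0})\,\alpha\, m_w}
                    {\varpi R T \rho_w}
      \left[\frac{1}{RWC_{LT}-a_f}
            \;-\;\frac{SWC_L\,\Lambda_E}
                      {(SWC_L\,RWC_{LT}\,c_w + c_{DM})\,T}\right],$$

implemented in `chi_w_closed()`.  The first bracket term is the
symplast-concentration effect of losing water and the second its
evaporative-cooling effect; with $\pi_{L,0}<0$ the cost is positive
whenever cooling dominates.  A noteworthy analytical fact: the
Weibull-apoplast feedback ($a_f$ responding to $\pi_L$, summarized by
the diagnostic `delta_term()`) multiplies *both* partial derivatives of
$\dot\pi_L$ and cancels exactly in the ratio, so it does not appear in
the cost evaluated at a fixed leaf state.  The equivalence of the closed
form and the finite-difference oracle to better than $10^{-6}$ relative
error over a factorial grid of hydration, temperature and prior-range
trait draws is part of the acceptance suite.

Three response directions follow directly and are enforced as tests:
the cost falls with leaf temperature (the $\Lambda_E/T$ term — warm
leaves price water cheaply because each mole of water removes less
heat relative to the osmotic benefit), rises as the leaf dehydrates
toward the turgor-loss point (for admissible trait sets; see the
filter below), and rises as the osmotic potential at full hydration
becomes more negative — the carbon-use feedback by which accumulating
foliar carbohydrates close stomata.

## From cost to conductance

`gw_from_lambda_closed()` inverts the marginal condition for a generic
one-branch photosynthesis model $A_n = f_0 (c_i - \Gamma^*)/(c_i +
\gamma) - R_d$.  Substituting the diffusion-demand coupling
$A_n = (g_w/1.6)(c_a - c_i)$ into the marginal condition and
normalizing by $x = (c_i-\Gamma^*)/(c_a-\Gamma^*)$ yields a quadratic

$$\bigl[1 - z(1-\rho)\bigr]x^2 - 2\bigl[1-\rho y\bigr]x +
  \bigl[1 - y + \rho y^2/z\bigr] = 0,$$

with $y = 1.6\lambda D_L/(P_{atm}(c_a-\Gamma^*))$,
$z = 1.6\lambda D_L/(P_{atm}(\Gamma^*+\gamma))$ and $\rho = R_d/f_0$;
the optimum is the root on $(x_0, 1)$ where $x_0$ marks zero net
assimilation.  A safeguarded bracketed solver of the same marginal
condition (`solve_branch_ci_safeguarded`) is retained purely as a
cross-check; the tests require agreement to near machine precision.

Both Farquhar branches (carboxylation: $f_0 = V_{c,max}$, $\gamma =
K_c(1+o_i/K_o)$; electron transport: $f_0 = J/4$, $\gamma = 2\Gamma^*$)
are solved.  Because the realized assimilation is the branch minimum,
the profit-maximizing conductance is the best of three candidates:
each branch optimum — valid only where its own branch is limiting —
and the co-limitation kink where the branches cross (the kink absorbs
an interval of water prices; there the one-sided marginal profits
bracket $\lambda$).  When $\lambda$ meets or exceeds the largest
attainable profit $\lambda_{max} = P_{atm}(c_a-c_{i,0})/(1.6 D_L)$ the
stomata close onto a cuticular floor $g_{0,min} = 0.005$ mol m$^{-2}$
s$^{-1}$ (configurable), which keeps transpiration well-defined in the
coupled model.

## Pressure-volume backbone

The leaf state is built on classical pressure-volume theory with a
variable apoplast: the apoplastic fraction is a Weibull function of the
osmotic potential, $a_f = a_{f,max}\exp(-(\pi_L/\pi_L^*)^\beta)$;
turgor follows a linear elastic segment with modulus $\varepsilon_{L,0}$
above the turgor-loss point and is clamped at zero below it; and the
osmotic potential at full hydration scales with absolute temperature
from its 25 °C reference.  On the solute-conservation manifold the
symplastic relative water content reduces to $\pi_{L,0}/\pi_L$, which
makes the inversion from observed water potential to full leaf state a
closed-form quadratic — the reason the calibration likelihood is fast.
Root solves elsewhere use bracketed bisection with an absolute
tolerance of $10^{-10}$ MPa.

# Tunable parameters

| Parameter | Units | Default | Why |
|---|---|---|---|
| `af_max`, `pi_L_star`, `beta` | –, MPa, – | 0.5, −2.45, 5 | Weibull apoplast response; the collapse of apoplastic water on dehydration is what steepens the cost near wilting |
| `eps_L0` | MPa | 5.2 | elastic modulus; sets the turgor-loss point together with `pi_L0_25` |
| `SWC_L` | kg kg⁻¹ | 1.4 | saturated water content; scales the leaf's thermal and water capacitance |
| `alpha` | mol mol⁻¹ | 2.3 | carbon atoms per first-formed osmolyte (triose phosphate ≈ 3); linear scale of the cost |
| `pi_L0_25` | MPa | −1.8 | osmotic potential at full hydration, 25 °C; treatment-specific |
| `c_DM` | J K⁻¹ kg⁻¹ | 500 | dry-matter specific heat |
| `g0_min` | mol m⁻² s⁻¹ | 0.005 | cuticular conductance floor |
| `k_max`, `d_k`, `Q10` | mol m⁻² s⁻¹ MPa⁻¹, MPa, – | 0.01, 1.2, 2 | exponential soil–plant conductance (per leaf area) |
| `sf`, `psi_f` | MPa⁻¹, MPa | 2, −2.5 | sigmoidal water-stress downregulation of capacities (coupled simulations only) |

The canonical trait set (`fixture_params()`) was chosen once to satisfy
the model's own admissibility constraints simultaneously: near-complete
stomatal closure at the wilting point (the calibration filter, see
below), a declining cost with leaf temperature at fixed hydration, and
a coupled temperature optimum of conductance between 20 and 30 °C.
These constraints genuinely compete — the same apoplast collapse that
closes stomata at wilting makes the apoplast temperature-sensitive
through $\pi_{L,0}\propto T$ — and the resolution is to spread the
collapse over a deep turgor-loss range ($\psi_{tlp} \approx -2.75$
MPa).  All values sit inside the calibration prior ranges.

# The whole-plant coupler

`solve_operating_point()` closes the loop between the leaf and its
water supply.  Demand at a prescribed leaf water potential follows from
the pipeline above, with the leaf-to-air VPD evaluated at the leaf
temperature that closes a minimalist energy balance (isothermal net
radiation, linearized longwave, two-sided sensible exchange,
evaporative cooling — linear in $T_L$, hence solved exactly); the inner
temperature iteration is damped by 0.5 with geometric extrapolation
once the step ratio settles.  Supply is Darcy flow through a single
lumped conductance evaluated at the leaf-end potential,
$k = k_{max}e^{\psi_L/d_k}Q_{10}^{(T-T_{ref})/10}$, whose maximum — the
critical transpiration — has the closed form $\psi_{crit} = \psi_s -
d_k$, $E_{crit} = k(\psi_{crit})\,d_k$.

All demand–supply intersections over $(\psi_s - 40\,d_k, \psi_s]$ are
classified: an intersection is dynamically stable when
supply-minus-demand decreases through zero as $\psi_L$ increases (the
leaf rehydrates when supply exceeds demand).  The solver returns the
stable subcritical root when one exists, otherwise a stable
supercritical root — a genuinely stable operating point on the falling
branch of the supply curve, which this class of lumped hydraulic model
admits — and otherwise flags desiccation with the state at maximum
supply.  Convergence tolerances are $10^{-8}$ (K and MPa) at the
returned point; time-series callers warm-start the root from the
previous step, falling back to a full scan whenever the local solve
fails or loses the subcritical branch.  Percent loss of conductance
uses the $\psi$-dependent factor only (temperature does not register
as damage).

# Ecosystem extension

`run_simulation()` drives the coupler through a root-zone bucket:
Campbell retention ($\psi_s = \psi_e(\theta/\theta_{sat})^{-b}$),
big-leaf mean-canopy light with extinction coefficient 0.5, soil–plant
conductance fixed per unit ground area (per-leaf conductance inversely
proportional to LAI), a single-coefficient equilibrium-evaporation
model for soil evaporation, half-hourly steps with the cuticular floor
at night and below 3 °C, no drainage below the root zone, and runoff
only above saturation.  Every step closes its water budget exactly
(the closure error is tracked and asserted below $10^{-12}$ m per step
and $10^{-9}$ m cumulatively over two years).  Mortality is flagged at
the first crossing of 50% and 85% loss of soil–plant conductance, and
days with supercritical water potentials are collected — the
machinery used to compare water-use strategies under drought.

The reference schemes share every component except the stomatal rule:
`uso_gw()` (the Medlyn unified-optimization form with its single slope
g1), `cowan_farquhar_gw()` (a constant marginal cost), and
`gain_risk_gw()` (instantaneous maximization of normalized carbon gain
minus normalized soil–plant conductance loss, searched over the
subcritical branch only, so it never returns supercritical states).

# Calibration

`run_mcmc()` fits six species-shared traits plus one treatment-specific
`pi_L0_25` to observed conductances with a Gaussian likelihood whose
noise SD is profiled (analytically when no observation sits on the
cuticular floor; numerically otherwise, because floor observations are
treated as left-censored — the statistically correct counterpart of
the generators' truncation, and without which the fitted osmotic
potential is biased about 20% deep), uniform priors over physiological
ranges, and the wilting-closure filter: trait combinations whose
modelled conductance at the turgor-loss point exceeds 5% of the
full-hydration value (reference environment, threshold inclusive and
configurable) are excluded from the prior.  The sampler is a
differential-evolution MCMC ($\gamma = 2.38/\sqrt{2d}$ with scaled
proposals, a unit-$\gamma$ mode-jumping generation every tenth step,
and a small uniform jitter), with split-chain potential-scale-reduction
diagnostics.

Two design points deserve explanation.  First, the filter admits well
under 0.1% of the prior box, so chains cannot be initialized by plain
rejection; the initializer pre-screens random draws on the
wilting-to-full-hydration cost ratio, scans the osmolyte size
$\alpha$ (the cost is exactly linear in it) to land inside the
admissible wedge, refines the best admissible point toward the
posterior mode with bounded Nelder-Mead, and starts two thirds of the
chains near that mode with the rest kept dispersed so the convergence
diagnostic stays meaningful.  Second, the posterior is strongly
ridged: the seven-trait vector is over-parameterized relative to the
smooth conductance surface the data constrain, and deeper-wilting
trait sets can mimic the same surface over the sampled water-potential
range.  At n = 500 observations the profile likelihood of `pi_L0_25`
is flat to within one log-unit across roughly ±20% of its value (its
maximum sits at the generating value under the censored likelihood),
so the posterior *median* drifts to the volume centroid of the ridge
while the posterior *mode* recovers the truth.  Recovery checks should
therefore weigh the mode and held-out predictive error, not the median
alone; the acceptance machinery reports all three.

# What the synthetic data emulate

`generate_gas_exchange()` emulates a leaf-level campaign: uniformly
drawn light, temperature and humidity over typical measurement ranges,
water potentials spanning full hydration to near the turgor-loss
point, the model's own optimal conductance, and iid Gaussian
observation noise truncated at the cuticular floor (a small positive
bias at low conductance, accepted and documented rather than
resampled).  `generate_forcing()` builds a two-year half-hourly series
with sinusoidal seasonal/diurnal envelopes, marked-Poisson rain
(~700 mm yr⁻¹), a seasonal LAI cycle, and a drought scenario that
multiplies the second summer's rain depths by 0.25 and adds a +3 K
anomaly — a normal-then-drought contrast.  What these generators do
*not* emulate: the covariance structure of real campaigns (light,
temperature and humidity co-vary in the field), instrument-specific
error structure, osmotic adjustment over a season, or species mixtures.
Passing tests therefore demonstrate internal consistency and
recoverability under the model's own assumptions, not field validity.

# Numerical choices

Problem sizes used by the test and acceptance runs are deliberate
choices: oracle grids of a few hundred points, calibration at n = 500
observations and 3000 DE-MC generations over 17 chains, and two
simulated years at half-hourly resolution — enough to exercise every
regime (wet, drought, supercritical, mortality) while keeping a full
run reproducible in minutes.  Ties in the branch choice resolve toward
carboxylation; degenerate inputs (non-positive VPD, water potentials
above zero, sub-residual water contents) raise typed errors at the
module boundary; and all random draws flow from explicit seeds through
a generator that restores the caller's RNG state.

# Known limitations

* **No reopening at extreme heat.**  Under this package's
  profit-consistent inversion, conductance necessarily declines
  monotonically at high temperature: the largest attainable marginal
  profit shrinks with VPD at roughly 6–8% K⁻¹ (Clausius–Clapeyron plus
  kinetics), faster than the marginal cost can fall (2–3% K⁻¹).
  Reopening "to cool the leaf" would require transpiring at negative
  net carbon balance, i.e. evaluating the conductance solution on the
  algebraic continuation $x > 1$ of the inversion quadratic.  That
  continuation exists for *any* price above $\lambda_{max}$, so
  admitting it would also hold stomata open at the wilting point and
  destroy the closure filter that the calibration depends on.  We keep
  the profit-consistent rule; the cost itself still declines with
  warming, and warming still opens stomata everywhere photosynthesis
  can pay for the water.
* The hydraulic pathway is a single lumped resistor evaluated at the
  leaf-end potential; spatially explicit schemes would remove the
  stable supercritical states this model predicts.
* The coupler is steady-state at the operating-point scale; the
  non-steady-state physics lives inside the cost, not in plant water
  storage dynamics.
* `pi_L0_25` is constant per treatment: no osmotic adjustment
  dynamics.
* No mesophyll conductance, no triose-phosphate limitation, no
  photosynthetic acclimation.

# A worked example

```{r example, eval = FALSE}
fx <- fixture_params()
env <- leaf_environment(T_air = 298.15, RH = 0.5)

# a moderately dehydrated leaf
st <- state_from_psi(-1.0, 298.15, fx$pv)
chi_w_closed(st, fx$pv)          # marginal cost of water (mol/mol)
optimal_gas_exchange(st, env, fx$photo, fx$pv)

# coupled operating point at a given soil water potential
solve_operating_point(-0.3, env, fx$photo, fx$pv, fx$hyd, fx$eb)

# two-year drought experiment, both schemes
f <- generate_forcing(years = 2, seed = 11)
pr <- list(pv = fx$pv, photo = fx$photo, hyd = fx$hyd_ground,
           eb = fx$eb, soil = fx$soil)
mortality_compare(run_simulation(f, pr, scheme = "gainrisk"),
                  run_simulation(f, pr, scheme = "chi_w"))
```
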