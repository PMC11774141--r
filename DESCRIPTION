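Package: stomopt
Title: Stomatal Optimization from Non-Steady-State Leaf Water, Carbon and
    Energy Storage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Gas-exchange modelling toolkit built around a stomatal
    optimality scheme in which the marginal carbon cost of water emerges
    from the non-steady-state physics of leaf water, solute and heat
    storage.  Implements leaf pressure-volume theory with a
    Weibull-varying apoplastic fraction, the marginal cost of water both
    mechanistically (rate-of-change of the mesophyll osmotic potential)
    and in closed form, a Farquhar-type photosynthesis model with a
    marginal-profit inversion to optimal stomatal conductance, a
    minimalist whole-plant coupler (leaf energy balance plus exponential
    soil-plant hydraulics with critical-point analysis), an ecosystem
    bucket-model drought simulator with hydraulic-failure mortality
    flags, reference stomatal schemes (Medlyn USO, constant marginal
    cost, Sperry-type Gain-Risk), differential-evolution MCMC
    calibration with a wilting-point closure filter, and seeded
    synthetic-data generators for all inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
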