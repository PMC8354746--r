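Package: reefsph
Title: Coral Habitat Engineering on a Weakly Compressible SPH Solver
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A two-dimensional weakly compressible smoothed-particle
    hydrodynamics (WCSPH) solver coupled to Goldilocks-Principle growth and
    death rules for cold-water coral framework. Fluid particles convert to
    live coral where the time-averaged local flow speed sits in the optimal
    prey-capture band; live coral converts to dead framework after a
    configurable interval of suboptimal flow. Includes the Wendland C2
    kernel, Tait equation of state, Morris laminar viscosity, density
    reinitialization, Verlet time integration with CFL-type step control,
    dynamic boundary particles, analytic validation cases (laminar channel,
    hydrostatic tank), scenario configuration/IO and a command-line entry
    point.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
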