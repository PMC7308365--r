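Package: nichesim
Title: Niche Construction Metapopulations on Ephemeral Lattice Landscapes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic spatial simulation of metapopulations that construct
    their own niche on an ephemeral landscape. Implements a contact-process-like
    interacting particle system on a periodic square lattice in which occupied
    patches go extinct, every patch is destroyed at a global rate, and niche
    constructors convert destroyed patches back into colonizable habitat at a
    cost to their colonization rate. Provides an exact continuous-time Gillespie
    simulator (with an optional exploiter strategy for scramble competition),
    the corresponding mean-field theory (equilibria, stability, saddle-node
    extinction thresholds, optimal construction allocation), and an experiment
    harness for phase diagrams, critical-point estimation, order-parameter
    exponent fits, relaxation profiles, range expansion from a single seed,
    and competition regime classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
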