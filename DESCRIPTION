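Package: tallowsim
Title: Spatially Explicit Bioeconomic Simulation of Chinese Tallow Invasion
Version: 0.1.0
Authors@R: person("tallowsim", "developers", role = c("aut", "cre"),
    email = "tallowsim@example.org")
Description: A stochastic, spatially explicit lattice model of Chinese tallow
    (Triadica sebifera) invasion of southern U.S. forestlands, coupled to
    discounted damage, search, and control cost accounting under
    threshold-based control policies. Provides logistic within-cell growth,
    lognormal-kernel dispersal with probabilistic colonization and a
    maturation delay, timber damage valuation from embedded productivity and
    stumpage-price tables, Monte Carlo scenario comparison, control-threshold
    sweeps with common random numbers, and a synthetic landscape generator
    emulating the structure of the Forest Inventory and Analysis grid.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
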