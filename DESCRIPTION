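Package: bioscrub
Title: Process Simulation and Techno-Environmental Assessment of Flue-Gas Bioscrubbers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dynamic plant model of a two-stage biological flue-gas
    desulfurization train (caustic spray absorber, sulfidogenic UASB
    reactor, microaerobic sulfide-oxidation CSTR with PI dissolved-oxygen
    control) coupled to model-driven life-cycle inventories, a midpoint
    impact-characterization layer with the Relative Impact Ratio statistic,
    life-cycle costing (net present value, cumulative present value,
    breakeven surfaces) and two-dimensional sensitivity sweeps comparing a
    conventional chemical scrubber against bioscrubber variants. Includes a
    pH charge-balance speciation solver, a data-driven stoichiometric
    reaction engine with sulfide inhibition, gas-liquid two-film mass
    transfer, energy-recovery accounting and deterministic synthetic
    fixture generation for assessment tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
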