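Package: protalloc
Title: Proteome-Constrained Kinetic Modeling of Yeast Central Carbon Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A resource-dependent kinetic model of Saccharomyces cerevisiae
    central carbon metabolism in which every lumped reaction is bounded by
    the proteome mass fraction allocated to it. Provides stiff ODE
    simulation of chemostat and periodic feast/famine feeding regimes,
    detection of steady states and balanced cycles, calibration of specific
    pathway activities (kcat) against flux and proteome data, Monte Carlo
    proteome evolution under steady-state and dynamic objectives, stepwise
    estimation of proteome overcapacity, and reporting of phenotype tables,
    enzyme saturation statistics and proteome-specific ATP yields. Includes
    a synthetic-fixture generator for protein tables and flux targets and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
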