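Package: kirflux
Title: Cycle-Flux Analysis of K+ and Water Permeation in Kir2.1 Channels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discrete-state kinetic modelling of coupled potassium and water
    permeation through the inward-rectifier channel Kir2.1. Implements an
    eleven-state permeation diagram (four selectivity-filter sites plus a
    lumped wide-pore K+ site), voltage-dependent rate evaluation with
    detailed-balance-dependent rates, exact steady-state solution and
    decomposition of the net flux into simple-cycle fluxes with per-cycle
    water:ion coupling ratios, streaming-potential data reduction (reversal
    potentials from voltage ramps, junction-potential correction, slope
    regression and ANCOVA), weighted Nelder-Mead rate-constant fitting with
    AIC model selection, and a seeded synthetic-data generator emulating
    single-channel current-voltage and osmotic-pulse experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
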