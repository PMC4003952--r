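Package: pbrsim
Title: Dynamic Simulation of an Outdoor Tubular Photobioreactor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Dynamic simulator of an outdoor fence-type tubular photobioreactor
    for microalgae culture. Couples a clearness-index solar radiation model, a
    lumped-volume (volume element) thermal model, liquid- and gas-phase mass
    balances for a perfectly mixed bubble column plus a plug-flow tubular loop
    (biomass, dissolved oxygen, total inorganic carbon), carbonate-system pH
    speciation, and low-level control loops for CO2 injection, culture
    circulation and culture temperature in manual, on/off, time-based PI and
    event-based (send-on-delta) PI modes, with ideal manual harvesting.
    Simulations are deterministic time-stepped runs driven by synthetic or
    recorded irradiance profiles; results are returned as plain data frames
    and can be written to CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
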