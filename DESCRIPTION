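Package: agarfilm
Title: Biofilm Growth Kinetics on an Agar Substrate
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the growth of a Bacillus subtilis biofilm colony on an
    agar plate with a four-variable ordinary-differential-equation model:
    mass balances for active and inactive biomass with Monod substrate
    uptake, a moving-boundary thickness equation, and Fickian nutrient
    diffusion from the agar reservoir across a laminar sublayer. Provides a
    stiff integrator front end with dense-output event detection (peak
    active fraction, substrate depletion, steady state), closed-form
    conservation-law oracles, a parameter-sweep engine for sensitivity
    directions, and a Beer-Lambert optical-density to thickness calibration
    with an attenuation-length fit and a synthetic profile generator.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
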