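Package: gripsim
Title: Lumped-Parameter Simulation of a Rotary Comb-Drive MEMS Cell Microgripper
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical models of a rotary electrostatic comb-drive MEMS
    microgripper for squeezing single biological cells: comb capacitance and
    electrostatic torque, push-pull drive signals and the side-instability
    voltage limit, Castigliano energy-method stiffness of the serpentine
    suspension with a space-frame beam oracle, slide-film air damping,
    Hertzian large-deformation cell contact with a cubic torque reduction,
    and the steady-state Duffing frequency response by Ritz averaging.
    Includes an inverse estimator that converts measured resonance shifts of
    the gripped device into the elastic modulus and stiffness of the cell,
    with cell-type classification against published reference moduli, plus
    synthetic-measurement generators for validating the inference chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
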