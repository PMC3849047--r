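Package: nanolung
Title: Multiscale Toxicodynamic Simulation of Nanoparticle Effects on Mouse Lung
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Coupled simulator of pulmonary surfactant homeostasis and inhaled
    nanoparticle biokinetics in the mouse alveolar region. Implements a
    five-compartment, three-species surfactant mass-balance model with
    regulatory kinetics and steady-state calibration, Michaelis-Menten binding
    of interfacial phospholipid to nanoparticle surface area, adhesion-weighted
    cellular uptake by alveolar epithelial cells and macrophages, first-order
    particle elimination, and a surfactant-coupled Constant Phase Model of
    respiratory impedance with spectrum fitting. Includes one-at-a-time local
    sensitivity analysis and synthetic-spectrum generation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    yaml,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
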