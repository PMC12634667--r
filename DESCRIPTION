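Package: mpsbarrier
Title: Pillar-Array Interfacial Barriers for Microphysiological Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computational characterization of pillar-array interfacial
    barriers in microfluidic microphysiological systems (MPS). Provides
    parametric barrier geometry (porosity, porous volume, hydraulic
    diameter), a reduced quasi-static two-phase simulator for capillary
    burst-valve behavior of straight versus pillar fenestrae, depth-averaged
    (Hele-Shaw) flow and albumin advection-diffusion across the barrier
    (Peclet numbers, permeability at half saturation, equilibration times),
    a three-dimensional Michaelis-Menten oxygen reaction-diffusion model of
    engineered cardiac microtissue run as a population of models over
    single-cell oxygen consumption variability, and a finite-size scaling
    collapse that estimates the allometric exponent relating tissue oxygen
    consumption to tissue mass. Synthetic-data generators reproduce the
    statistical structure every stage assumes, and a small orchestration
    layer drives configured runs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    grDevices,
    graphics,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
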