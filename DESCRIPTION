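Package: epsim
Title: Coupled Electro-Thermal Simulation of Electroporation-Based Tissue Treatments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Finite-difference simulator for electroporation-based tumor
    treatments (electrochemotherapy, irreversible electroporation, gene
    electrotransfer, H-FIRE) on a uniform three-dimensional grid. Couples a
    variable-coefficient Laplace equation for the electric potential, with
    temperature-dependent tissue conductivity, to Pennes' bioheat equation
    with Joule heating, blood perfusion and convective electrode cooling.
    Pulse trains and bipolar high-frequency bursts drive a staged ON/OFF
    simulation loop that records electrode current, delivered charge, probe
    temperatures, and electroporated and damaged tissue volumes under a
    pulse-number-dependent electric-field threshold; includes ready-to-run
    protocol presets, pulse-number dose tuning, and legacy VTK/CSV output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
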