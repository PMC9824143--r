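Package: membranr
Title: Bilayer Diffraction, Calorimetry, Infrared and Trajectory Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for model phospholipid membranes: full q-range
    small-angle X-ray diffraction fitting with a three-Gaussian electron
    density profile and steric bilayer thickness extraction, wide-angle
    chain-packing deconvolution and phase classification, differential
    scanning calorimetry processing (baseline, tangent onset/completion,
    enthalpy, partial phase diagrams and immiscibility detection), ester
    carbonyl infrared band decomposition, and geometric statistics on
    molecular-dynamics-style configurations (area per lipid, phosphorus
    thickness, hydrogen bonds, mass density profiles, solute clustering).
    Includes seeded synthetic generators that emulate each instrument and
    simulation output so the whole pipeline is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    signal,
    pracma,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    bio3d,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
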