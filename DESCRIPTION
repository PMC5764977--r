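Package: guvscan
Title: Microwave Split-Ring-Resonator Scanning of Giant Unilamellar Vesicles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward and inverse modelling for microfluidic split-ring-resonator
    (SRR) scanning of giant unilamellar vesicle (GUV) membranes. Provides an
    equivalent-circuit model of a microstrip line coupled to a split-ring
    resonator producing complex S21 spectra at the odd resonance modes, a
    quasi-static two-dimensional field solver for the sub-micron split gap over
    a layered dielectric stack (capacitance, sensitivity kernels, parallel-field
    energy fraction, elevation attenuation), an inversion pipeline that maps an
    observed change in S21 to a complex in-plane membrane permittivity, a
    scan-trace analysis stage (change-point segmentation, per-section
    transmission change, lipid-domain classification, cohort statistics), and a
    synthetic-trace generator whose presets reproduce the statistical structure
    of published GUV scan measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
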