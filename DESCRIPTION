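Package: platecal
Title: Microplate Dilution-Scheme Design, Liquid-Handling Error Simulation,
    and Robust Calibration-Curve Construction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for the metrology of automated liquid handling on 96-well
    microplates, organised around the construction of absorbance calibration
    curves. Generates geometric (serial, column-to-column) and linear (direct,
    reservoir-to-well) dilution plate maps and the transfer-instruction lists
    that realise them; simulates their execution under parameterised pipetting
    error models (independent volume noise, systematic gains, carryover in
    iterative transfers, reservoir concentration error, contamination droplets,
    per-repeat transient excursions) and renders wells-by-wavelengths
    absorbance plates from a configurable carotenoid-like solute spectrum;
    decomposes measured plates into a shared nonnegative solute spectrum, a
    blank-anchored baseline, and per-well abundances; assesses transfer errors
    by regression inversion with per-well residual and relative-error maps,
    per-wavelength correlation scans, and stratified column/row trend analysis;
    and aggregates technical repeats by outlier-resistant repeat filtration
    before fitting robust linear or quadratic calibration curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
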