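Package: paddydose
Title: Tillering-Stage Nitrogen Prescription for Rice from Canopy
    Hyperspectra and Crop-Model Data Assimilation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding the tillering-stage nitrogen topdress in paddy
    rice. Aboveground biomass is inverted from canopy reflectance spectra using
    successive-projections band selection and an extreme learning machine, the
    inverted biomass is assimilated into a daily nitrogen-limited crop growth
    engine by an ensemble Kalman filter or windowed four-dimensional
    variational analysis, and the corrected state is used to search the
    smallest tillering nitrogen dose that brings simulated yield to a target,
    emitting a per-zone variable-rate prescription map (urea equivalent).
    Includes a synthetic-data module (endmember-mixing spectra, weather,
    plot layouts, twin-experiment truths) so the whole chain is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
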