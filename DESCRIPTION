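Package: smtkit
Title: Single-Molecule Tracking Analysis of Competence-Pilin Membrane Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the membrane dynamics of bacterial competence pilins
    from single-molecule tracking data. Implements squared-displacement (SQD)
    and jump-distance mixture inference of apparent diffusion coefficients and
    population fractions with model selection, confidence intervals and
    simultaneous (shared-D) multi-condition fits; per-track confinement
    classification against a localization-error-derived radius; projection of
    localizations into a standardized rod-shaped cell with density maps; a
    seeded simulator of two-state membrane diffusion on spherocylindrical
    cells, surface filaments and photobleaching traces for validation; and
    accessory morphometric and assay calculations (filament arc lengths,
    pilus-positive cell fractions, transformation frequency, dye-mass).
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
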