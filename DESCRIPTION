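Package: micellar
Title: Micellization Analysis of Surfactant Titration Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Infers micellization descriptors of ionic surfactants from the
    four classical titration experiments: critical micelle concentration (CMC)
    and degree of counterion dissociation from two-segment break-point
    regression of conductivity curves; maximum surface excess, minimum
    headgroup area and critical packing parameter from Gibbs adsorption
    analysis of surface-tension curves; CMC from the pyrene I1/I3
    micropolarity probe; and micelle hydration (hydrated molecular volume,
    bound water and cosolvent counts) from an Einstein-type virial expansion
    of relative viscosity with prolate-rod shape factors. Includes a seeded
    forward simulator for all four measurement types so every estimator can
    be validated by parameter recovery, plus CSV readers and a JSON report
    pipeline tailored to fluorinated surfactants such as ammonium
    perfluorooctanoate (APFO) in water/urea media.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
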