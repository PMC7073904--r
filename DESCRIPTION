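Package: c1flux
Title: In Vivo Formaldehyde-Tetrahydrofolate Condensation Flux from Growth
    Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives the in vivo rate of the spontaneous condensation of
    formaldehyde with tetrahydrofolate (THF) from measured growth rates of
    engineered Escherichia coli one-carbon auxotrophs. Provides a small
    constraint-based modelling toolkit (BiGG-style JSON and SBML/FBC model
    input, declarative model curation, flux balance analysis, phenotypic
    phase planes), exponential growth-curve fitting, Nash-assay calibration,
    rate-law evaluation for the spontaneous condensation, seeded synthetic
    data generators for every input, and an orchestrated analysis that
    converts measured growth rates into a condensation flux and into a
    maximal growth-rate bound for an organism assimilating formaldehyde
    solely through this reaction via the serine cycle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
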