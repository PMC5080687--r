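Package: ibferm
Title: Carbon and Redox Balance Analysis of Isopropanol-Butanol Fermentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing clostridial isopropanol-butanol (IB)
    fermentations on glucose, glycerol and their mixtures. Computes mass
    yields, overall volumetric productivities, butanol/isopropanol ratios,
    consumed-carbon totals, NAD(P)H generation and requirement bookkeeping,
    the ferredoxin-derived NAD(P)H fraction, per-carbon-mole product
    normalisation and carbon recoveries from endpoint tables or time
    courses. Ships a chemical species registry with redox stoichiometric
    coefficients, reader/writers for endpoint and time-course tables, a
    deterministic biphasic (acidogenic/solventogenic) batch fermentation
    simulator for end-to-end testing, and a command-line report tool.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
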