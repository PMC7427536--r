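Package: rhamnoflux
Title: Stoichiometric and Bioprocess Analysis of Rhamnolipid Production from Ethanol
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing heterologous mono-rhamnolipid production by
    Pseudomonas putida growing on ethanol. Provides a curated core
    stoichiometric model of ethanol metabolism with a mono-rhamnolipid
    pathway extension and PQQ- versus NAD-dependent cofactor scenarios, a
    flux balance analysis engine with a parsimonious tie-break and yield
    accounting (Cmol, mmol per mmol, biomass), SBML Level 3 FBC import and
    export, a dynamic fed-batch fermentation simulator with dissolved-oxygen
    triggered ethanol pulse feeding and foam recirculation, fermentation
    analytics (four-parameter logistic fits, growth rates, space-time and
    acetate-corrected yields), qPCR 2^dCt quantification with primer
    efficiency estimation, and seeded synthetic-data generators for all of
    the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
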