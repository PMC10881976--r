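Package: fluxenv
Title: Bicarbonate-Constrained Production Envelopes for 3-Hydroxypropionate
    Production in Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Constraint-based analysis of 3-hydroxypropionic acid (3-HP)
    production in Saccharomyces cerevisiae under limited bicarbonate supply.
    Provides stoichiometric model structures with SBML (Level 3 + FBC) and
    native JSON input, flux balance analysis with deterministic parsimonious
    optima, editing helpers that graft the malonyl-CoA reductase pathway onto
    a model and cap or open bicarbonate supply relative to glucose uptake,
    production-envelope sweeps over growth rate and bicarbonate availability,
    overlay of fermentation endpoints onto the envelope plane, yield and unit
    arithmetic, an inorganic-carbon speciation calculator, and a curated
    yeast central-carbon core model plus synthetic strain tables for testing.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
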