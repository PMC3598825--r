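Package: fermbalance
Title: Stoichiometric Balancing of Lignocellulose Fermentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for black-box stoichiometric analysis of mixed-acid
    fermentations on lignocellulosic substrates. Converts biomass
    compositional data (glucan, xylan and other polymer mass fractions)
    into monosaccharide molar equivalents, computes theoretical
    ethanol+acetate+lactate product capacities and substrate-utilization
    statistics, closes carbon and available-electron (degree-of-reduction)
    recovery balances including cell biomass via the empirical per-carbon
    formula CH2N0.25O0.5, and summarizes replicated mono- and co-culture
    experiment records. A synthetic-data generator produces
    stoichiometrically closed fermentation outcomes and time courses for
    validating the whole pipeline and for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
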