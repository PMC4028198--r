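Package: mzgroupnet
Title: Mass-Difference Transformation Networks and Pathway Inference for
    Time-Series LC-MS Metabolomics
Version: 0.1.0
Authors@R:
    person("mzgroupnet", "developers", role = c("aut", "cre"),
           email = "mzgroupnet@example.org")
Description: Detects chemical and biochemical transformations between
    high-mass-accuracy m/z features by comparing elemental-composition
    differences of their candidate sum formulas against a user-editable
    rules file, assembles the matches into a time-consistent directed
    network, enumerates non-redundant (maximal) pathways, ranks rule
    frequencies, proposes recurrent unlisted mass differences as novel
    modifications, and maps formulas onto van Krevelen (O/C vs H/C)
    coordinates. Ships an exhaustive candidate-formula generator, a
    56-rule default transformation list, a synthetic time-series fixture
    generator built around an anthocyanin acylation/glycosylation chain,
    Pajek network export, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
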