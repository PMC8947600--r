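Package: ngmcs
Title: Nutrient-Genetic Minimal Cut Sets for Constraint-Based Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Enumerates nutrient-genetic minimal cut sets (ngMCSs): minimal
    combinations of gene losses and/or environmental nutrient deprivations
    that block biomass production in a constraint-based metabolic model.
    Builds the binary G matrix from gene-protein-reaction boolean rules,
    augments it with one pseudo-gene row per nutrient in the growth medium,
    and enumerates shortest cut sets by mixed-integer optimisation over a
    Farkas-duality encoding of "biomass blocked", with LP verification of
    every solution. Includes a rule that maps expression data (TPM) and
    medium composition onto the cut sets to call context-specific essential
    genes and nutrient auxotrophies, toy and random fixture generators, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
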