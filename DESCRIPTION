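Package: cyanoflux
Title: Constraint-Based Metabolic Modelling of Photoautotrophic Cyanobacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-scale constraint-based analysis of
    photoautotrophic metabolism: SBML (Level 3 + FBC v2) model input/output,
    construction of biomass objective functions from measured macromolecular
    composition (including the elemental biomass formula, degree of reduction
    and photosynthetic quotient), flux balance analysis and parsimonious FBA
    under photoautotrophic constraints, model-curation checks (biomass
    precursor gaps, thermodynamically infeasible loops, ATP-from-nothing),
    single-reaction essentiality screening, growth/non-growth associated
    maintenance sensitivity scans, and maximum theoretical product yields for
    native and heterologous compounds. Includes a generator of small synthetic
    photoautotroph models with analytically known optima for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    Matrix,
    xml2,
    yaml,
    jsonlite,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    boot,
    optparse,
    withr
Config/testthat/edition: 3
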