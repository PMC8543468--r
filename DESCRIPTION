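Package: margeflux
Title: Relative-Expression and Exometabolome Constrained Flux Balance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based metabolic modeling tools for predicting flux
    redistribution between two experimental conditions. Implements MARGE, a
    two-step linear program that couples two flux states through relative
    enzyme expression (enzyme usage variables derived from gene-protein-
    reaction rules) and then applies a parsimonious enzyme usage criterion;
    converts extracellular metabolomics (spent-medium profiles against a
    pure-medium baseline) into uptake/secretion direction, magnitude-floor and
    between-condition ratio constraints on exchange fluxes; and scores
    reporter metabolites by aggregating gene-level statistics over the
    metabolic network with a permutation background. Ships a deterministic
    branched toy network and seeded generators of condition-paired expression
    and exometabolome data for end-to-end testing, plus SBML (Level 3 fbc) and
    native JSON model input/output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
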