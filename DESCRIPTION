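Package: ascoflux
Title: Constraint-Based Prediction of Overexpression Targets for
    Polyketide Overproduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for deriving product-specific constraint-based metabolic
    models from a base genome-scale reconstruction, computing wild-type flux
    references by flux balance analysis (FBA), simulating enzyme
    overexpression by amplifying individual fluxes and re-solving with
    minimization of metabolic adjustment (MOMA), and ranking candidate
    targets by the f_PH score (the product of the perturbed-to-wild biomass
    and product flux ratios).  Includes readers and writers for SBML
    Level 3 (FBC), a documented JSON dialect and a TSV reaction-table
    dialect; model curation operations (subsystem removal, reaction
    addition, bound edits, ethylmalonyl-CoA pathway completion); a
    threshold-based metabolic-enzyme conservation analysis over pairwise
    protein-alignment hit tables; and deterministic synthetic-data
    generators for desk-scale validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    grDevices,
    jsonlite,
    quadprog,
    stats,
    tools,
    utils,
    xml2
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
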