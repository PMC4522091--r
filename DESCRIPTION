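Package: redoxscreen
Title: Model-Driven Prediction of Redox Cofactor Engineering Targets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based screening of NAD(H)/NADP(H)-dependent reactions
    for redox cofactor engineering in stoichiometric metabolic models.
    Computes a parsimonious flux balance analysis (FBA) reference state,
    filters candidate oxidoreductases, simulates knockout, overexpression
    and NAD(H) to NADP(H) cofactor-swap perturbations over factor grids by
    minimization of metabolic adjustment (MOMA), and ranks perturbations by
    the phenotypic fraction f_PH = f_biomass * f_isobutanol^2.  Ships a toy
    microaerobic, pflB-deleted E. coli-like network with an
    NADPH-dependent isobutanol pathway as test substrate, readers and
    writers for BiGG-style JSON and SBML Level 3 FBC models, cofactor
    flux-sum balance sheets, and the closed-form fermentation arithmetic
    (titer changes, molar yields, NADPH demand) used to interpret
    fermentation outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    quadprog,
    stats,
    utils,
    xml2
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
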