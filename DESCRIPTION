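Package: meltsol
Title: Amino-Acid Solubility Prediction from Fast-Scanning-Calorimetry
    Melting Properties with PC-SAFT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts aqueous solubility of amino acids from experimentally
    measured melting properties. Implements the PC-SAFT equation of state
    (hard-chain, dispersion and Wertheim 2B association contributions) for
    associating mixtures, activity and osmotic coefficients of aqueous
    amino-acid solutions, solid-liquid-equilibrium solubility prediction from
    melting temperature and enthalpy of fusion, binary-interaction-parameter
    fitting to osmotic-coefficient data, and the reduction of fast scanning
    calorimetry (FSC) thermograms to melting temperature, molar enthalpy of
    fusion and entropy of fusion with uncertainties. Seeded synthetic-data
    generators emulate FSC scan sets and solution-property tables with
    planted ground truth so that every stage of the pipeline is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
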