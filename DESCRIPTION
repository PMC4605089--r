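Package: htlplatform
Title: Mass, Energy and Techno-Economic Accounting for Co-Solvent
    Hydrothermal Liquefaction of Oleaginous Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing hydrothermal liquefaction (HTL) experiments
    on oleaginous yeast biomass: product-slate mass balances and chemical
    energy recovery, carbon-hydrogen recovery and elemental atomic ratios,
    slurry sensible-heat and binary-solvent critical-point estimates, a
    conceptual fermentation-to-fuel biorefinery mass-flow model with
    nutrient recycle, and a discounted-cash-flow techno-economic engine
    with a minimum-fuel-selling-price solver and one-at-a-time sensitivity
    analysis.  A synthetic replicate generator reproduces the statistical
    structure of duplicate batch-reactor runs so every pipeline stage is
    testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
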