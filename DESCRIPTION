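Package: hdxmix
Title: Intrinsic Amide Hydrogen-Deuterium Exchange Rates in H2O/D2O Mixtures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes intrinsic (chemical) forward and back amide
    hydrogen-deuterium exchange rates of unstructured peptides in
    H2O/D2O mixtures as functions of solvent deuterium fraction,
    acidity, temperature and sequence. Provides operational acidity
    scale conversions (pH* read, pL, pOL) with the mixture ionic
    product, isotope-resolved base-catalysed reference rates with
    Arrhenius temperature scaling and published side-chain
    (lambda/rho) sequence factors, per-residue forward/back/total
    pseudo-first-order rates, equilibrium deuterium enrichment and
    amide fractionation factors, exponential uptake curves, and
    protection-factor-attenuated observed rates. Includes a
    command-line interface and deterministic fixture generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
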