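Package: cablecensus
Title: Quantification of Cable Bacteria Abundance and Activity in Marine Sediments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A quantitative pipeline from raw sediment measurements to a census of
    electrogenic cable bacteria. Computes diffusive fluxes from microsensor
    pore-water depth profiles (Fick's first law with tortuosity correction),
    total-sulfide speciation from H2S and pH, and the oxic/suboxic/sulfidic
    zonation that fingerprints electrogenic sulfur oxidation. Fits qPCR standard
    curves and converts Cq values into 16S rRNA gene copy densities per gram of
    wet sediment, and from these derives cell and filament length densities,
    per-filament electrical current, per-cell oxygen consumption and growth
    timing via electron mass balances. Includes IUPAC-degenerate primer
    evaluation (expansion, mismatch-tolerant binding-site search, in-silico PCR,
    design-rule QC, taxonomy-aware specificity screening) and amplicon
    relative-abundance cross-validation, together with a seeded synthetic-data
    generator that plants ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
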