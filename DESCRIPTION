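Package: hexasense
Title: Quantifying 1,6-Hexanediol Sensitivity of Chromatin Proteins and Genome Architecture
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to quantify the sensitivity of chromatin-associated proteins
    and higher-order chromatin structure to 1,6-hexanediol, a compound that
    dissolves hydrophobic-interaction-dependent biomolecular condensates.
    Computes the anti-1,6-hexanediol index of chromatin-associated proteins
    (AICAP) from label-free proteomics abundance tables (iBAQ to
    fraction-of-total conversion, minimum-value imputation, quantile
    normalization, Welch tests, preranked set enrichment, residue-composition
    correlation), and measures chromatin-structure responses from paired
    before/after Hi-C contact matrices: Knight-Ruiz balancing,
    observed-over-expected transforms, A/B compartment calling and change
    classification, insulation-score TAD boundary detection and matching,
    aggregate peak analysis of loops, differential loops, stripe aggregation,
    and FRAP recovery-curve fitting. Includes synthetic-data generators with
    planted ground truth so every stage is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    minpack.lm,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
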