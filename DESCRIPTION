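Package: inscount
Title: Quantification Pipeline for Digital Barcode-Count Expression Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the complete quantification procedure for
    nCounter-style digital molecular-barcode expression data: spike-in
    (positive-control) and target-sum normalization, negative-control and
    deletion-calibrated background modeling with detection calling, RNA
    input-mass titration QC, replicate coefficient-of-variation analysis,
    spike-in standard curves, cross-platform concordance, life-cycle stage
    profiling with expression-pattern classification, and qPCR
    cross-validation (genomic-DNA standard curves, Ct to copy-number
    conversion, reference-gene normalization). Includes a seeded synthetic
    data generator with Poisson-lognormal counting noise so that every
    pipeline stage is testable with known ground truth, and a configurable
    end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
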