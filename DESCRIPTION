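Package: refstab
Title: Reference-Gene Stability Analysis for RT-qPCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A desk-scale toolkit for selecting stably expressed reference
    (housekeeping) genes from RT-qPCR quantification-cycle (Cq) data.
    Provides replicate-level quality control (Cq cutoff filtering,
    negative-control contamination flags, intra- and inter-assay
    coefficients of variation), standard-curve fitting with amplification
    efficiency estimation from the slope, four expression-stability
    algorithms (geNorm, NormFinder, BestKeeper, comparative delta-Ct), a
    RefFinder-style geometric-mean aggregation, a five-algorithm rank-sum
    consensus with inter-algorithm correlation, and a seeded synthetic Cq
    generator with planted gene stabilities so every stage of the pipeline
    can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
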