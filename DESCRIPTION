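Package: isletmir
Title: Differential miRNA Expression in Sorted Pancreatic Islet Cell
    Types from qPCR Array Ct Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis of TaqMan low-density-array (TLDA) miRNA
    profiling data from paired, FACS-sorted pancreatic alpha- and
    beta-cell preparations. Implements threshold-cycle (Ct) censoring
    at the instrument detection limit, detection filtering across
    donors, endogenous-control (RNU48-style) normalization, paired
    delta-delta-Ct fold changes, a from-scratch one-class Significance
    Analysis of Microarrays (SAM) with sign-flip permutation null and
    q-values, and intersection of cell-type-enriched miRNAs with
    miRNA-to-gene target-prediction databases and islet gene groups.
    Includes a synthetic Ct-data generator with planted enrichment
    effects, donor-shared noise, endogenous-control drift and
    detection-limit censoring so that every pipeline stage can be
    tested without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
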