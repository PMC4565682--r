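Package: crossmir
Title: Cross-Platform Small RNA Biomarker Discovery and Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for standardised discovery and validation of circulating
    small-RNA biomarkers across sequencing and RT-qPCR platforms. Implements
    isomiR-tolerant read counting against a mature miRNA reference,
    consensus differential expression under RPKM, quantile and TMM
    normalisation with Welch t-tests and Benjamini-Hochberg correction,
    effect-size and power calculations via the noncentral t distribution,
    RT-qPCR absolute quantification from standard curves with amplification
    efficiency QC, spike-in based enrichment-process normalisation, and a
    seedable synthetic-data generator emulating whole-blood small-RNA
    profiles and quantification-cycle data with precursor contamination.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    edgeR,
    jsonlite,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
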