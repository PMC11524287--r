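Package: refstable
Title: Reference Gene Discovery from RNA-Seq Counts with RT-qPCR Stability
    Validation and Universal Primer Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A protocol for identifying candidate reference genes for RT-qPCR
    normalization from compendia of RNA-Seq count data. Implements four
    count-normalization methods (FPKM, TPM, trimmed mean of M-values, and
    median-of-ratios size factors) from first principles, screens stably
    expressed genes by the coefficient of variation of log2(x+1) expression,
    ranks candidate genes from quantification-cycle (Ct) tables with the
    delta-Ct, geNorm, NormFinder and BestKeeper stability statistics combined
    by a geometric-mean comprehensive rank, estimates amplification efficiency
    from dilution standard curves, and designs genus-level universal primer
    pairs on consensus sequences of orthologous transcripts with in-silico
    cross-genome specificity checks. Includes seeded simulators for count
    matrices, Ct tables and diverged ortholog sequence sets with planted
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    DESeq2,
    jsonlite,
    withr
Config/testthat/edition: 3
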