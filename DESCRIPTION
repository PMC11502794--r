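Package: epipattern
Title: Multi-Omic Differential Methylation, Hydroxymethylation and
    Expression Pattern Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Differential analysis and integration of reduced-representation
    bisulfite sequencing (RRBS) 5mC counts, reduced-representation
    hydroxymethylation profiling (RRHP) 5hmC tag counts, and RNA-seq gene
    counts. Calls differentially methylated loci with a beta-binomial
    dispersion-shrinkage Wald test, differentially hydroxymethylated loci and
    differentially expressed genes with a negative-binomial Wald test under
    median-of-ratios normalization, annotates significant loci to genes by
    2 kb extension and interval merging, assigns each gene a combinatorial
    epigenetic detection pattern per differentiation stage, classifies
    pattern trackability across differentiation, and detects reciprocal
    5mC/5hmC switching between differentiation environments. Ships a
    synthetic count-data generator with planted ground truth for calibration
    and recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    yaml,
    withr,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
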