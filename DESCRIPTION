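Package: rdcnv
Title: Exome Read-Depth CNV Association Scanning and Copy-Number Genotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects common copy number variants (CNVs) associated with
    case-control status from exome-capture read depth. Per-base depths are
    normalized by sample mean coverage, summarized per capture region by a
    streaming power-iteration first principal component, and cleaned of
    cohort-wide technical structure (batch, GC) by projecting out global
    principal components of the stacked local components. Cleaned summaries
    are tested for association with disease by logistic regression with
    genomic-control, quantile-quantile and GC-bias diagnostics. At associated
    loci, absolute copy-number genotypes (CN 0-4) are obtained from 100-bp
    window depths via a population Gaussian-emission hidden Markov model
    fitted by expectation maximization, with per-sample call certainties. A
    synthetic-cohort generator (Hardy-Weinberg CNV genotypes, logistic
    disease model, negative-binomial depth with batch and GC structure) makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    withr,
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
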