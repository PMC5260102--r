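Package: glints
Title: Disease-Specific Prioritization of Coding and Flanking Noncoding SNVs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Prioritizes candidate single nucleotide variants (SNVs) for a
    query disease by integrating heterogeneous variant-level functional
    scores with gene-level disease-association evidence. Variants are
    classified into exonic (nonsynonymous), promoter, near-boundary
    intronic and canonical splice-site regions; region-appropriate
    functional scores and gene-disease association statistics from a
    multivariate phenotype-similarity regression are calibrated to
    empirical p-values against empirical null panels; the per-variant
    p-values are then combined with Fisher's statistic under a
    dependence-corrected scaled chi-squared null and converted to pFDR
    q-values. Includes a synthetic-data generator for spike-in
    benchmarking and the associated rank-based evaluation metrics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
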