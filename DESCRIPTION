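Package: pdachet
Title: Multi-Region Multi-Omics Heterogeneity Analysis for Pancreatic Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing intra- and inter-tumoural heterogeneity in
    multi-region sequencing studies of pancreatic ductal adenocarcinoma.
    Implements somatic-variant filtering and tumour mutational burden,
    copy-number burden, weighted genome instability index and arm-level
    event calling, cancer-cell-fraction based clonality and genome-doubling
    relative mutation timing, clone-tree reconstruction with trunk/branch
    statistics and downsampled driver-gene fold enrichment, a conservative
    posterior fold-change statistic for replicate-free differential
    expression, private/shared differentially methylated region
    classification with phyloepigenetic trees, cross-omics rank correlation,
    and clinical association statistics (Fisher tests, Kaplan-Meier and
    log-rank by copy-number burden group). A synthetic multi-region cohort
    generator with full ground truth drives testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    mclust,
    utils,
    survival,
    ape,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    phangorn
Config/testthat/edition: 3
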