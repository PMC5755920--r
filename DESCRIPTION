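Package: methdomains
Title: Methylation Domain Segmentation, Sequence Classification, and
    Ectopic Methylation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for asking whether genomic sequence determines its own
    DNA methylation state. Segments per-CpG bisulfite methylation calls
    into hypomethylated and hypermethylated domains, classifies domain
    sequences with a class-weighted k-mer spectrum linear SVM (with
    optional CpG masking and stratified cross-validated precision-recall
    evaluation), quantifies the correlation between endogenous and
    ectopic methylation of reintegrated genomic fragments, computes
    methylation and editing rates from Sanger trace peak heights, and
    simulates every required input (genomes with CpG-dense hypomethylated
    islands, beta-binomial methylomes, MspI-captured fragments, ectopic
    readouts under competing models, and noisy traces).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    Rcpp,
    withr
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
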