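Package: zfpopgen
Title: Population Genomics of Wild and Laboratory Zebrafish
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Within- and among-population diversity and differentiation
    statistics for biallelic SNP genotypes and mitochondrial haplotype
    alignments, a hierarchical island-model coalescent null distribution for
    FDIST-style F_ST outlier detection, and post-hoc genome scans for outlier
    clustering, selective-sweep heterozygosity valleys and elevated or
    decaying linkage disequilibrium. Ships a synthetic-data generator that
    emulates hierarchically structured SNP datasets with plantable selective
    sweeps and clade-structured mitochondrial alignments, so every analysis
    can be exercised end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    vcfR,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
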