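Package: bulkmapr
Title: Bulked-Segregant (QTL-seq) Mapping with Simulated F2 Populations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for mapping recessive trait loci from bulked-segregant
    whole-genome sequencing of F2 populations. Implements two-stage SNP
    filtering (site-quality hard filters and pool-informativeness filters),
    per-SNP association statistics (Euclidean distance raised to the fifth
    power, and the delta SNP-index with simulated confidence bands), fixed
    SNP-count window fitting, candidate-region calling, and interval
    intersection across reciprocal populations. A synthetic-data module
    simulates F2 meiosis with recombination, recessive phenotype
    architectures, extreme-bulk selection, and pooled read-depth sampling,
    providing ground truth for every downstream stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    vcfR,
    IRanges,
    GenomicRanges,
    rtracklayer,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
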