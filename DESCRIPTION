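Package: coddiag
Title: Diagnostic SNP Discovery and Species Assignment for Cod Products
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reference-free discovery of species-diagnostic SNPs from
    restriction-site associated DNA (RAD) sequencing reads and assignment of
    commercial cod products to species. Implements de novo RAD-tag stacking
    into per-sample loci and a cross-sample catalog, quality-aware genotype
    calling, and a two-clause diagnostic filter selecting sites where each
    species is fixed for a distinct allele. Also provides COI barcode
    assignment by best-hit percent identity with a neighbor-joining grouping
    check, an in-silico PCR amplicon genotyper housing a published
    five-SNP/two-amplicon panel for Gadus morhua, Reinhardtius
    hippoglossoides and Dissostichus eleginoides, and a seeded simulator of
    TaqI-anchored RAD reads and COI-like barcodes that provides ground truth
    for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    VariantAnnotation,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, SNP, SequenceMatching, Alignment
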