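Package: strainSNP
Title: Transcriptome SNP Discovery and Multi-Strain Comparison from Pileups
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quality- and depth-filtered SNP calling from per-strain
    samtools mpileup text against a reference transcriptome, with
    ORF-aware functional classification of variants (UTR, synonymous,
    missense, premature-stop, stop-loss), set algebra over multiple
    strains (intra-strain, inter-strain, strain-specific, non-redundant
    and shared SNP sets), and descriptive summaries (minor allele
    frequency histograms, transition/transversion ratios, per-contig
    SNP distributions, gene-interval binning, validation rates). A
    seeded synthetic-data generator simulates multi-contig cDNA
    references with embedded open reading frames, implanted per-strain
    allele configurations and pileups at configurable depth, base
    quality and error rate, so the whole pipeline is testable without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    GenomicRanges,
    SummarizedExperiment,
    BiocGenerics,
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: SNP, VariantDetection, VariantAnnotation, Transcriptomics, Sequencing
RoxygenNote: 7.3.3
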