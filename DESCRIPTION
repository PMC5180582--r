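Package: gbskit
Title: Genotyping-by-Sequencing Marker Discovery and Association Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and analysis toolkit for two-enzyme genotyping-by-sequencing
    (GBS) studies. Provides in silico single and double restriction digestion of
    genome FASTA with IUPAC-degenerate recognition sites, fragment size selection
    and length histograms; closed-form expected marker yield and shared-SNP
    retention models under Poisson sequencing depth; paired-read quality control
    with site-prefix, ambiguous-base and sliding-window quality rules; composite
    SNP filtering on per-genotype depth, site quality and population call rate;
    genotype concordance statistics against an independent assay; SNP location
    and coding-effect annotation against GFF3 gene models; and single-marker
    association scans with a sex covariate plus REML variance-component
    partitioning on genomic relationship matrices. A synthetic-data module
    generates genomes, populations, observed genotypes, reads and phenotypes
    with truth tables so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
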