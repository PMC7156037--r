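Package: bsamapr
Title: Bulk Segregant Mapping-by-Sequencing and Genomic Enrichment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for mapping EMS-induced causal mutations in Arabidopsis
    thaliana by pooled F2 bulk-segregant sequencing: EMS-spectrum (G:C to A:T)
    variant filtering, allele-frequency zygosity classification, 500-kb
    windowed homozygote/heterozygote ratio scans, and linkage-interval
    calling. Companion statistics for downstream locus sets: chi-square
    enrichment of loci in pericentromeres versus chromosome arms, chromatin
    state overlap fractions, Fisher's exact tests of gene-set overlaps,
    promoter motif scanning with a random-gene resampling null, differential
    expression threshold filtering, 2^-ddCt relative expression and NSAF
    spectral-count scoring. A synthetic-data generator with known ground
    truth (simulated genomes, selected F2 pools under a Haldane map,
    promoter sets with embedded motifs) makes every stage testable without
    external sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
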