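Package: popsweep
Title: Composite Selective-Sweep Scans from Phased Haplotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects positive selection between two diverged populations
    (for example highland versus lowland) from phased, ancestrally
    polarized SNP haplotypes. Implements per-SNP Weir-Cockerham F_ST,
    derived-allele-frequency difference (dDAF), extended haplotype
    homozygosity (EHH) curves, iHS and cross-population XP-EHH, and their
    integration into the iFXD product-of-odds composite statistic with
    gene-level aggregation, ranking, and sliding-window empirical p-value
    scans. Includes Mann-Whitney U gene-set enrichment tests (for example
    cancer-gene catalogues versus the genomic background), a small
    contingency-table module for tissue-microarray positivity and
    association statistics, and a two-population Wright-Fisher forward
    simulator with selective sweeps that provides full ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    vcfR,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
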