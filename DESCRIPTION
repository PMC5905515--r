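Package: sweepscan
Title: Selective-Sweep Scanning and Validation for Multi-Population SNP Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sliding-window selective-sweep discovery from biallelic SNP
    genotypes: Weir-Cockerham F_ST and pooled-heterozygosity (Hp) log-ratio
    scans with joint top-5% thresholds, merged sweep regions and flank-based
    candidate-gene assignment; per-window nucleotide diversity, Watterson's
    theta and Tajima's D; population-structure utilities (F_ST and
    allele-sharing distances, neighbor-joining trees, genotype PCA, two-locus
    EM haplotype frequencies, D', r-squared, LD decay and pruning);
    candidate-SNP association testing under additive, dominant and recessive
    codings with covariates; relative expression by the 2^-ddCt method; and a
    seeded Balding-Nichols cohort simulator with sweep injection so the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    ape,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
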