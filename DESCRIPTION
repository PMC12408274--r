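Package: flockscan
Title: Genomic Inbreeding, Diversity and Composite Selection Scans for SNP Array Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Within-population genomic analysis of livestock SNP-array panels:
    PLINK-format genotype input/output with call-rate quality control, LD
    pruning and kinship filtering; runs-of-homozygosity detection with
    L-parameter minimum SNP thresholds and four genomic inbreeding
    coefficients (F_ROH, F_GRM, F_HOM, F_IS); pairwise Weir-Cockerham FST;
    linkage-disequilibrium-decay historical effective population size;
    five within-population selection statistics (iHS, H12, ZHp, nucleotide
    diversity, Tajima's D) merged into a decorrelated composite of multiple
    signals (DCMS) with Gaussian calibration and Benjamini-Hochberg FDR
    control; and a forward Wright-Fisher simulator of multi-population
    diploid SNP data with recombination, migration, bottlenecks, small-flock
    mating and hard sweeps used to exercise every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
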