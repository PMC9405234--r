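Package: ldsweep
Title: Linkage Disequilibrium, Haplotype Blocks, Effective Population Size
    and Haplotype-Based Selection Scans for SNP Chip Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A population-genomics workflow for diploid SNP array data from
    small, closed livestock populations. Provides genotype/haplotype
    containers with PLINK bed/bim/fam and VCF readers and writers,
    per-population quality control (exact Hardy-Weinberg test, call rate,
    minor allele frequency, method-of-moments IBD relatedness pruning, PCA),
    pairwise r-squared linkage disequilibrium with distance-binned decay
    curves, Gabriel-definition haplotype block detection with D-prime
    confidence intervals and cross-herd block comparison, linkage
    disequilibrium based historical effective population size trajectories,
    extended-haplotype-homozygosity selection scans (iHS with
    frequency-binned standardization and a two-sided neutrality p transform,
    and cross-population XP-EHH), candidate-region annotation against
    gene/QTL intervals, and a forward Wright-Fisher simulator with
    configurable population-size history and hard selective sweeps that
    serves as a ground-truth test substrate for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
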