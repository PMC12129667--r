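Package: divescan
Title: Two-Stage Selection Scan and Association Testing for Isolated
    Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a two-stage population-genetic analysis for detecting
    recent positive selection in a focal population and linking candidate loci
    to a quantitative phenotype. Stage one is a per-SNP likelihood-ratio test
    for excess allele-frequency change in the focal population relative to the
    genome-wide covariance of outgroup-rooted frequency contrasts, with a
    zero-inflation-aware genomic-control calibration based on upper quantiles
    and a point-mass/chi-square mixture p-value. Stage two applies windowed
    peak selection to the scan statistics and tests the resulting candidate
    SNPs for covariate-adjusted additive association with the phenotype under
    Bonferroni control. Supporting tools cover variant and sample QC (minor
    allele frequency, heterozygote-excess exact test, relatedness pruning,
    allele-flip detection between merged panels), population-structure
    statistics (Weir-Cockerham FST, windowed nucleotide diversity and
    effective population size, genotype PCA), and a Balding-Nichols drift
    simulator that generates genotypes, phenotypes, and injected artifacts
    with the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    vcfR,
    withr
Suggests:
    GenomicRanges,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
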