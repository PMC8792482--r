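Package: reefgen
Title: Seascape Genomics of Natural and Hatchery-Restored Shellfish Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-genomic analysis of natural and hatchery-restored
    shellfish reefs from biallelic SNP genotypes: per-site diversity
    (observed and expected heterozygosity, rarefied allelic richness, FIS
    with bootstrap intervals, Ritland relatedness, standardized multilocus
    heterozygosity), linkage-disequilibrium-based effective population size
    with jackknife intervals and a life-history bias adjustment, LD-decay
    SNP thinning via a critical R-squared and LOESS crossing, PCA- and
    FST-based outlier scans with a neutral/outlier/adaptive partition,
    Weir-Cockerham pairwise FST, Mantel isolation-by-distance, DAPC-style
    clustering, redundancy-analysis genotype-environment association with
    robust Mahalanobis outliers, spatial eigenvector (PCNM) construction
    and environment-versus-geography variance partitioning, and models
    linking hatchery practices to genetic diversity. Includes a
    forward-time Wright-Fisher simulator of demes on an environmental
    gradient with migration, recombination, selection, and hatchery
    planting, emitting genotypes plus ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    vcfR,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
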