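Package: sweepscan
Title: Selection Scans and Population Differentiation from Phased Haplotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A selection-scan and population-differentiation workflow for
    phased, bi-allelic SNP data: quality-control filtering with LD thinning,
    allele-frequency statistics (per-individual inbreeding F, windowed
    Tajima's D, Weir-Cockerham F_ST), haplotype statistics (EHH decay, iHH,
    standardized iHS and cross-population xpEHH), the three-population f3
    admixture test with block-jackknife Z-scores, windowed sweep calling with
    top-quantile significance, and per-gene rank-sum evidence integration.
    Ships a forward-in-time Wright-Fisher simulator of phased diploid
    haplotypes (population splits, pulse admixture, hard selective sweeps)
    so every stage is testable end to end on synthetic cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
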