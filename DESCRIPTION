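Package: popstructr
Title: Population Structure and Heterotic Group Analysis for Inbred SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the population-genomic characterization of structured
    inbred panels genotyped at genome-wide SNPs: quality-control filtering,
    per-locus and windowed diversity statistics (MAF, gene diversity, PIC,
    heterozygosity), linkage-disequilibrium structure and decay-distance
    estimation, Gabriel-style haplotype blocks and tagSNP selection, genomic
    kinship, an admixture-model fit with EM and cross-validation for choosing
    the number of ancestral groups, Wright's Fst differentiation with UPGMA
    trees, a rule-based heterotic-group assignment from admixture proportions,
    and classification of group-specific SNP loci. Includes a Balding-Nichols
    structured-population simulator with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    vcfR,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    cluster,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
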