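Package: beakscan
Title: Selection-Signature Scanning and Marker Validation for Two-Population Genotype Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects selective sweeps between two phenotype-labelled duck
    populations from biallelic SNP genotypes and validates candidate marker
    loci. Implements sliding-window nucleotide diversity (theta-pi), weighted
    Weir-Cockerham F_ST, the log2 pi-ratio tail-intersection rule for calling
    swept regions, gene annotation of merged regions, genotype PCA,
    extreme-difference locus filtering, EM estimation of two-locus haplotype
    frequencies with D, D' and r2, genotype/allele chi-square association,
    and relative expression by the 2^-ddCt method. Ships a two-population
    genotype simulator with a planted divergent region and the genotype-count
    tables for the MITF beak-colour marker, so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tools,
    utils,
    vcfR
Suggests:
    cluster,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
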