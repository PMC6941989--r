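Package: supergene
Title: Comparative Population Genetics of Mimicry Supergene Loci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting the evolutionary history of a shared
    mimicry supergene across closely related species. Implements windowed
    Weir-Cockerham F_ST and Tajima's D with genome-wide percentile
    enrichment, Haploview-style D'/LOD linkage disequilibrium, per-SNP
    genotype-phenotype association with Benjamini-Hochberg FDR, genome-wide
    versus locus-restricted PCA with heterozygote calling, Sawyer-style
    gene-conversion tract detection with permutation significance,
    neighbour-joining allelic genealogies with clustering-mode and
    branch-elongation signatures, and a forward-time Wright-Fisher
    simulator of multiple diverging species carrying a supergene under
    negative frequency-dependent selection. A scenario discriminator
    combines these signatures to distinguish introgression, incomplete
    lineage sorting, allelic turnover, and independent origin of the
    shared locus.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
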