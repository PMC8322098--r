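Package: glpop
Title: Genotype-Likelihood Population Genomics for Multi-Colony Seabird Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Low-coverage population-genomic inference from genotype
    likelihoods: site-frequency-spectrum estimation by EM, nucleotide
    diversity and Tajima's D, individual heterozygosity, runs of
    homozygosity and F_RoH, Hudson F_ST from 2D spectra with Slatkin
    linearization, f3- and D-statistics with block-jackknife Z-scores,
    genotype-likelihood PCA and admixture-proportion EM with Evanno
    delta-K model choice, p-distance neighbor-joining trees with block
    bootstrap, least-cost sea distances with Mantel/MRM
    isolation-by-distance tests, and mitochondrial haplotype diversity,
    Phi_ST and hierarchical AMOVA.  Ships a synthetic multi-colony data
    generator so every stage is testable without sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    Rcpp,
    ape,
    igraph,
    geosphere
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    vegan,
    cluster,
    vcfR,
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
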