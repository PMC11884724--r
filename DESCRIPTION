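Package: ssrpop
Title: Microsatellite Diversity and Population Structure Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of codominant microsatellite (SSR) genotype tables from
    allele fragment sizes to population-genetic summaries: per-locus diversity
    statistics (major allele frequency, allele counts, gene diversity, PIC,
    observed heterozygosity), per-population allelic patterns (effective
    alleles, Shannon index, private and locally common alleles, unbiased
    expected heterozygosity, fixation index), Wright F-statistics and gene
    flow, Nei genetic distances, distance-based AMOVA with permutation tests,
    principal coordinates analysis, UPGMA dendrograms with Newick export, and
    Bayesian admixture clustering (STRUCTURE-type correlated-frequencies model)
    with Evanno delta-K model selection. Includes a Balding-Nichols simulator
    of SSR datasets with controlled differentiation, inbreeding, admixture and
    missingness, and readers/writers for GenAlEx-style codominant and long
    genotype tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    phangorn,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
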