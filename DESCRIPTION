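Package: haplopop
Title: Single-Locus Haplotype Diversity, Population Structure and
    Demographic Inference for mtDNA Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the classical single-locus population-genetic
    analysis of aligned haploid (mitochondrial) sequences: haplotype
    identification and count tables, haplotype and nucleotide diversity,
    two-level AMOVA and pairwise Phi-ST with permutation tests, Tajima's D
    and Fu's Fs neutrality tests with coalescent-simulated null
    distributions, mismatch distributions with sudden-expansion model
    fitting (tau, theta0, theta1, SSD, raggedness) and expansion-time
    dating, median-joining haplotype networks, neighbour-joining trees
    with bootstrap support, and a coalescent simulator (constant-size,
    sudden-expansion and island demographies) used for testing and for
    null distributions. Results are returned as tibbles with broom-style
    tidy() and glance() methods and ggplot2 autoplot() visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
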