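Package: sdpopgen
Title: Population Genetics and Structural Diversity of Segmental-Duplication Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed selection statistics (Tajima's D, Fay and Wu's H) with
    empirical and coalescent-simulation null distributions, copy-number
    population differentiation (V_ST and permutation tests), interlocus
    gene-conversion tract detection from sequence-identity profiles, and
    haplotype PCA clustering with resampling tests, for the analysis of
    complex segmental-duplication loci. Includes a structured-coalescent
    simulator (growth, population splits, ancient sampling) and generators
    for population-structured copy-number genotypes and diverged duplicate
    sequence pairs with planted gene-conversion tracts, so the full pipeline
    is testable on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
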