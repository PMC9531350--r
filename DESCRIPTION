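Package: prspipe
Title: Individualised Polygenic Risk Score Pipelines with Population Backgrounds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for applying published polygenic risk scores (PRS) to
    individual whole-genome variant data. Curates PGS-Catalog-style scoring
    files against explicit design and bioinformatic criteria, harmonises
    effect alleles with a reference panel, extracts allelic dosages from VCF
    genotypes, computes additive per-variant-weighted scores, places
    individuals as percentiles within population background distributions,
    translates percentiles into published odds or hazard ratios, and analyses
    trio inheritance (mid-parent averaging) and cross-population consistency
    of percentile assignments. A seeded synthetic-data generator (Balding-
    Nichols stratified cohorts, Hardy-Weinberg genotypes, Mendelian trios)
    makes every stage testable without access to private genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
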