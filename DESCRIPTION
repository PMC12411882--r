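Package: ratiotax
Title: Multivariate Ratio Analysis and Multilocus Distances for Integrative Taxonomy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for integrative species delimitation combining morphometric
    ratio analysis with multilocus sequence comparison. Implements multivariate
    ratio analysis of positive linear measurements: isometric size (geometric
    mean), principal components in log-ratio shape space, PCA and allometry
    ratio spectra with bootstrap confidence intervals, and a two-group linear
    discriminant ratio extractor that ranks body ratios by standard distance
    and decomposes group separation into size and shape components (delta).
    Also provides a molecular workflow for pre-aligned loci: alignment
    trimming, haplotype collapsing, multilocus concatenation with a haplotype
    ledger, Kimura two-parameter distances under complete or pairwise deletion,
    and within/between group distance summaries. Seeded simulators generate
    morphometric tables and two-clade haplotype sets with the statistical
    structure the analyses assume.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
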