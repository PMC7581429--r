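Package: varcascade
Title: Family-Based Variant Prioritization and Rare-Variant Burden Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Implements a family-quintet variant prioritization cascade for
    congenital heart disease gene discovery (genotype quality control,
    rarity and functional-impact filtering, inheritance-mode classification
    with compound-heterozygote transmission phasing and unaffected-sibling
    exclusion, and intersection with differential-expression evidence), and
    a case-control rare-variant burden framework (Hardy-Weinberg exact
    test, beta(1,25)-weighted burden/SKAT statistics combined via SKAT-O,
    category-stratified analyses, carrier enrichment, and ancestry
    subsetting). Ships seeded synthetic-data generators emulating a
    sequenced family of five and a case-control cohort so every stage is
    testable without access to protected genomes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    readr,
    ggplot2,
    jsonlite,
    withr,
    vcfR,
    Biostrings,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
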