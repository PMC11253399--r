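Package: oacevo
Title: Multi-Region, Multi-Timepoint Tumour Evolution Analysis for
    Oesophageal Adenocarcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyses intra-tumour heterogeneity and treatment-induced
    genomic evolution from multi-region, multi-timepoint somatic mutation
    calls. Classifies mutations into shared/private and unique-pre/unique-post
    populations, refits COSMIC-style SBS-96 mutational-signature exposures
    with a two-threshold selection-and-pruning protocol, scores platinum
    mutagenesis enrichment (C>A in CpC context within mutation-centred
    windows), decomposes tumours into clones by binomial-mixture clustering
    of multi-sample read counts, summarises neoantigen differential
    agretopicity, and associates signature presence with disease-specific
    survival. Includes a seeded synthetic-cohort generator so every stage is
    testable without access to restricted patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    quadprog,
    survival,
    jsonlite,
    Biostrings,
    stats,
    utils
Suggests:
    vcfR,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
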