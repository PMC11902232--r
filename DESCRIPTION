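Package: painlink
Title: Linking Oral Microbiome Variation to Host Gene Expression via
    Induced Visceral Pain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A correlation-screening pipeline that links oral-microbiome OTU
    abundance to peripheral-blood gene expression through a continuous
    induced visceral pain (IVP) phenotype. Provides readers and validators
    for phenotype, OTU abundance, taxonomy, and expression tables; a
    synthetic multi-omics cohort generator with planted, known correlation
    and occupancy structure; phenotype summaries with responder
    identification; a microarray expression preprocessing chain
    (global-mean normalization, natural-log scaling to a target mean,
    probe-to-gene summarization); Pearson correlation screening against IVP
    with Bonferroni correction; OTU-by-gene cross-correlation with
    family-level linkage matrices and species rosters; presence/absence
    occupancy profiling with differential commonness and exclusivity flags;
    and per-OTU differential abundance between clinical groups.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
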