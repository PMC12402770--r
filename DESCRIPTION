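Package: pedcan
Title: Consensus Somatic Calling, Tumor Mutation Burden, and WHO 2021
    Molecular Subtyping for Pediatric CNS Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream computational core for pediatric cancer cohort
    genomics: multi-caller consensus somatic SNV calling with
    multinucleotide-variant reconstruction and hotspot rescue, reciprocal
    overlap consensus copy-number calling, focal (gene/cytoband/arm level)
    copy-number status resolution, all-mutation and coding-only tumor
    mutation burden, gene-fusion prioritization, TP53 status annotation,
    and a WHO-2021-aligned rule engine assigning molecular subtypes to
    CNS tumor events from integrated SNV, CNV, fusion, expression, and
    methylation-classifier evidence. Ships a seeded synthetic-cohort
    generator with planted ground truth so every stage is testable
    without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    stringr,
    readr,
    rlang,
    ggplot2,
    generics,
    IRanges (>= 2.30.0),
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
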