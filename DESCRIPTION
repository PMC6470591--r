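Package: ddimine
Title: Resampling-Based Mining of Drug-Drug Interaction Terms from PubMed Literature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies substance terms (compounds and proteins) associated with
    drug-drug interactions of a query drug from MEDLINE-format literature
    records. Records are split into interaction-indexed and background groups;
    each candidate substance's co-occurrence frequency in the interaction group
    is compared against an empirical null distribution built by repeated random
    sampling from the background group, giving a Z-score and one-sided normal
    p-value per term, with Benjamini-Hochberg control of the false discovery
    rate. Significant terms are assembled into a weighted co-occurrence network
    exportable as GraphML or an edge list. Includes a synthetic MEDLINE corpus
    generator with known term-inclusion probabilities for calibration and
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
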