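Package: mbescope
Title: Targeting Scope and Outcome Quantification for Miniature CRISPR
    Base Editors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for working with hypercompact (Cas12f-derived) adenine
    and cytosine base editors: a curated registry of editor specifications
    (PAM, coordinate convention, activity and precision windows, sequence
    context preference), enumeration of oriented PAM placements on DNA
    sequences, classification of pathogenic SNVs as correctable or
    precisely correctable with bystander prediction, installation sgRNA
    design, quantification of editing outcomes from amplicon reads
    (per-position substitution matrices, editing-window profiles, product
    purity, allele homogeneity, context preference, on-to-off-target
    ratios and R-loop statistics), hard filtering and edit-class counting
    for RNA-seq variant calls, and a seeded simulator that generates every
    input the pipeline consumes with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
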