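Package: crisprselect
Title: Design and Quantitative Analysis of CRISPR-Select Variant Selection Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the CRISPR-Select functional variant assay: rule-based
    design of knock-in cassettes (SpCas9 guide selection with seed/PAM
    disruption, variant and synonymous WT-prime ssODN repair templates with
    45-nt homology arms, target-site primer placement outside the
    ssODN-covered region), classification of amplicon sequencing reads into
    editing-outcome allele categories, absolute cell-number estimation from
    genomic template mass, internally normalized variant:WT-prime selection
    analysis with frameshift-InDel controls and paired tests, sequencing-depth
    power guidance, single-cell biallelic zygosity tabulation, and a seeded
    forward simulator of edited cell populations that emits FASTQ plus truth
    tables so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
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
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
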