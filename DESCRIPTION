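Package: cryocurate
Title: Curation and Ecological Analysis of Ice-Core Metagenomic Sequence Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning multiplexed ice-core sequencing reads into
    curated per-sample community profiles. Provides multiplex-identifier
    (MID) demultiplexing with primer and adapter clipping, curation of
    tabular nucleotide homology-search results (identity and e-value
    thresholds, negative-control decontamination, best-hit deduplication,
    read enumeration, molecule-class assignment), declarative trait
    annotation of detected taxa (habitat source, physiology, metabolic
    capability), Shannon-Weaver diversity and cross-sample overlap
    accounting, and a mixed-effects negative-binomial regression of
    species counts on geochemical covariates with habitat as a random
    intercept. A seeded synthetic-community generator emulates the full
    study design (decorated reads, planted contaminants, decoy hits) so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    glmmTMB,
    MASS,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    knitr,
    rmarkdown
Config/testthat/edition: 3
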