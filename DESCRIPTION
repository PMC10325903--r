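Package: coopselex
Title: Predicting Cooperative Homodimer DNA Binding from HT-SELEX Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mines multi-cycle HT-SELEX read pools for transcription-factor
    homodimer binding sites and predicts cooperative DNA binding. Long
    enriched motifs are screened for two high-information-content 4-mer core
    sites, the enrichment rates of dimer versus monomer sites across
    selection cycles are compared through an enrichment factor, and
    spacer-length specificity is assessed by counting two-site
    configurations at every spacer length and orientation with Grubbs
    outlier and chi-square independence tests. Also quantifies
    cooperativity (Tau) from EMSA band proportions, and ships a synthetic
    SELEX/EMSA simulator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
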