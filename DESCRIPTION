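Package: ntermscope
Title: N-Terminome Annotation and Targeting-Peptide Cleavage Concordance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of protein N-terminomics data from TAILS-style
    reductive-dimethylation experiments. Provides decoy-based filtering of
    peptide-spectrum matches, mapping of N-terminal peptides to proteoform
    start indices, classification of in-vivo N-terminal modification states
    (free, acetylated, monomethylated, pyroglutamate) from isotopic
    labeling-chemistry mass shifts, concordance of observed N-termini with
    predicted organellar targeting-peptide cleavage sites within a signed
    offset window, modification-stratified position-frequency matrices for
    sequence logos, triage of acetylated N-termini at mitochondrial
    presequence cleavage sites, and a ground-truthed synthetic data
    generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
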