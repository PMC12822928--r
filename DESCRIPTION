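Package: calcproteo
Title: Authentication and Dietary Analysis of Ancient Dental Calculus Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-search inference chain for shotgun proteomics of
    archaeological dental calculus: target-decoy FDR filtering of
    peptide-spectrum matches (PSMs), oral-signature authentication of
    samples against oral-microbiome/salivary and contaminant reference
    lists, bulk asparagine/glutamine deamidation analysis with
    contaminant-versus-endogenous comparison, spectral validation of
    low-scoring dietary PSMs against predicted b/y fragment spectra,
    deamidation-aware taxonomic assignment of milk peptides, and
    per-individual/per-site summarization. Includes a synthetic-study
    generator with a fully recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
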