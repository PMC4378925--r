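Package: contamsort
Title: Contaminant-Aware Secretome Analysis with Composite Protein Databases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for handling fetal bovine serum (FBS) contamination in
    shotgun proteomic analyses of human cell secretomes. Builds composite
    protein search databases (human plus profiled FBS sequences), performs
    in-silico tryptic digestion and cross-species peptide specificity
    classification, filters and groups peptide-spectrum matches (PSMs)
    with charge-dependent XCorr and q-value criteria, compares search
    results across databases by posterior error probability, audits SILAC
    heavy-label incorporation at the residue and protein level, and
    generates fully seeded synthetic proteomes and PSM tables with known
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
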