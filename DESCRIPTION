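Package: biopepsim
Title: In Silico Proteolysis and Bioactive Peptide Release Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates complete enzymatic hydrolysis of proteins with
    rule-based cleavage specificities (P4-P4' positional constraints),
    matches intact sequences and released fragments against a
    peptide-bioactivity table, and computes the quantitative release
    parameters used to profile proteins as sources of bioactive peptides:
    the frequency of occurrence A (with major/moderate/minor binning), the
    frequency of release A_E, the relative release W, and the theoretical
    degree of hydrolysis DH_t. Includes a collagen-like synthetic sequence
    generator with planted motifs and an independent brute-force oracle,
    peptide-to-SMILES construction with neutral-pH ionization, and Lipinski
    Rule-of-5 descriptor evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ChemmineOB,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
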