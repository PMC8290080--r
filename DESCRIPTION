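Package: venomLP
Title: Discovery and Census of Linear Peptides in Spider Venom-Gland
    Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A rule-based pipeline for identifying linear (cytolytic)
    peptides encoded in spider venom-gland transcriptomes. Precursor
    proteins are segmented into signal peptide, acidic propeptide, mature
    peptides and anionic linkers by a processing-quadruplet-motif (PQM and
    inverted PQM) grammar solved as an exact dynamic program; mature
    peptides are characterised biochemically (average mass, isoelectric
    point, charge and hydrophobicity composition, C-terminal amidation);
    catalogs support the census arithmetic (simple, binary and complex
    precursor shares, cross-species peptide sharing, linker inventories),
    TPM-based abundance summaries, and a from-first-principles Poisson
    regression of peptide counts on phylogenetic root-to-tip depth. A
    seeded synthetic-precursor generator with known ground truth makes
    every stage testable without sequence downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
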