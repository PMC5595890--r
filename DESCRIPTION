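Package: smmipseq
Title: Targeted RNA Sequencing with Single-Molecule Molecular Inversion Probes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An open pipeline for smMIP-based targeted RNA sequencing. Designs
    single-molecule molecular inversion probe (smMIP) panels against spliced
    transcript models under the standard structural constraints (112-nt
    gap-fill, minimum 16/18-nt extension/ligation arms, 40-nt backbone, 8-nt
    unique molecule identifier, exon-junction preference), simulates capture,
    PCR duplication and paired-end 2x151 sequencing of the resulting
    amplicons, collapses PCR duplicates into unique reads by UMI consensus,
    quantifies expression as fragments per million (FPM) per smMIP and per
    transcript with TPM concordance analysis, and calls and annotates
    single-nucleotide variants and small deletions in the captured gap-fill
    regions with HGVS-style coding consequences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
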