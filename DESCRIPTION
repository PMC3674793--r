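Package: sigscaf
Title: Contig Scaffolding for Prokaryotic Draft Genomes from Inversion Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Orders and orients the contigs of a prokaryotic draft genome
    against a closely related reference genome by exploiting inversion
    signatures: breakpoints between conserved blocks whose two blocks lie on
    opposite strands, which mark the two ends of a large-scale inversion.
    Provides signed-permutation algebra (inversions, breakpoints, strips,
    inversion-signature pairing, inversion classes), construction of conserved
    blocks from whole-genome alignment match tables, a linear-time
    signature-driven scaffolding algorithm, scaffold quality metrics (correct
    contig adjacencies and length-weighted genome coverage), a seeded
    simulator of inversion-rearranged fragmented genomes, and a command-line
    interface with FASTA, tabular and AGP output.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    optparse,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
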