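Package: introntools
Title: Intron Retention Detection and Structural Comparison of Transcript Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing transcript annotations and adjusting transcript
    assemblies for intron-retention bias. Reads GTF files across Ensembl, RefSeq,
    CHM13, StringTie2 and Scallop2 dialects; extracts intron-exon boundaries,
    splice junctions and intron chains; measures structural similarity of two
    annotations with Jaccard indices at the boundary, junction and intron-chain
    levels; constructs gene correspondences via shared boundaries; detects
    transcripts with (partial) retained introns using three geometric criteria
    gated by an abundance ratio, and extracts or filters them from an assembly;
    and evaluates assemblies against reference annotations with intron-chain
    matching, precision, adjusted precision and biotype stratification. Includes
    a deterministic synthetic-annotation generator and brute-force oracles so the
    whole toolchain is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
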