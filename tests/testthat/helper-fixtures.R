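# shorthand transcript builder used across test files
tx <- function(id, exons, gene = "G1", chrom = "chr1", strand = "+",
               abundance = NA_real_, biotype = NA_character_) {
  transcript_model(id, gene, chrom, strand, exons,
                   abundance = abundance, biotype = biotype)
}

ann <- function(...) annotation_set(list(...))

# small random annotation for property sweeps
small_annotation <- function(seed, n_genes = 3L) {
  random_annotation(fixture_params(seed = seed, n_genes = n_genes,
                                   max_transcripts = 3L, max_exons = 5L))
}
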