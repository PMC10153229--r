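# Gene correspondence between two annotations. Two genes pair when they
# share at least one intron-exon boundary; each pair is scored with the
# per-pair Jaccard similarities at the boundary, junction and intron-chain
# levels. Only multi-exon genes participate, since single-exon genes carry no
# boundaries to pair on.

#' Restrict an annotation to its multi-exon genes
#'
#' A multi-exon gene is a gene with at least one transcript having two or
#' more exons. Such genes are kept with *all* their transcripts (including
#' any single-exon ones); genes with only single-exon transcripts are
#' dropped.
#'
#' @param x An [annotation_set()].
#' @return An [annotation_set()] containing the multi-exon genes.
#' @export
multi_exon_genes <- function(x) {
  stopifnot(inherits(x, "annotation_set"))
  if (!length(x$transcripts)) return(x)
  nex <- vapply(x$transcripts, function(t) nrow(t$exons), 0L)
  gids <- vapply(x$transcripts, `[[`, "", "gene_id")
  keep_genes <- unique(gids[nex >= 2L])
  .subset_annotation(x, names(x$transcripts)[gids %in% keep_genes])
}

.gene_sets <- function(x, ignore_strand) {
  ann <- multi_exon_genes(x)
  sets <- lapply(names(ann$genes), function(g)
    structure_sets(gene_of(ann, g), ignore_strand = ignore_strand))
  names(sets) <- names(ann$genes)
  sets
}

.pair_row <- function(g1, g2, s1, s2) {
  shared_b <- length(intersect(s1$boundaries, s2$boundaries))
  data.frame(gene1_id = g1, gene2_id = g2,
             j_boundary = jaccard_index(s1$boundaries, s2$boundaries),
             j_junction = jaccard_index(s1$junctions, s2$junctions),
             j_chain = jaccard_index(s1$chains, s2$chains),
             shared_boundary_count = shared_b,
             stringsAsFactors = FALSE)
}

#' Construct the gene correspondence between two annotations
#'
#' Over the multi-exon genes of each annotation, emits a pair `(g1, g2)` for
#' every cross-annotation gene pair sharing at least one intron-exon boundary
#' (default) or, with `pair_on = "junction"`, at least one junction. One gene
#' may appear in multiple pairs; no greedy resolution is attempted, as genes
#' within one annotation rarely share boundaries. Candidate pairs are found
#' through an element-to-gene inverted index rather than an all-pairs scan
#' (see [pair_genes_bruteforce()] for the naive reference implementation).
#'
#' @param t1,t2 Two [annotation_set()] objects.
#' @param pair_on Structural element whose sharing defines a pair:
#'   `"boundary"` (default) or `"junction"`. Junction sharing implies boundary
#'   sharing, so `"junction"` yields a subset of the `"boundary"` pairs.
#' @param ignore_strand Drop strand from element identity.
#' @return A data frame with columns `gene1_id`, `gene2_id`, `j_boundary`,
#'   `j_junction`, `j_chain`, `shared_boundary_count`, ordered by
#'   (`gene1_id`, `gene2_id`). Every emitted pair has `j_boundary > 0`.
#' @export
pair_genes <- function(t1, t2, pair_on = c("boundary", "junction"),
                       ignore_strand = FALSE) {
  pair_on <- match.arg(pair_on)
  field <- if (pair_on == "boundary") "boundaries" else "junctions"
  sets1 <- .gene_sets(t1, ignore_strand)
  sets2 <- .gene_sets(t2, ignore_strand)
  empty <- data.frame(gene1_id = character(), gene2_id = character(),
                      j_boundary = numeric(), j_junction = numeric(),
                      j_chain = numeric(), shared_boundary_count = integer(),
                      stringsAsFactors = FALSE)
  if (!length(sets1) || !length(sets2)) return(empty)
  # inverted index: element -> gene ids of t2
  elems2 <- lapply(sets2, `[[`, field)
  idx <- split(rep(names(elems2), lengths(elems2)),
               unlist(elems2, use.names = FALSE))
  rows <- list()
  for (g1 in names(sets1)) {
    hits <- idx[sets1[[g1]][[field]]]
    cand <- unique(unlist(hits, use.names = FALSE))
    if (is.null(cand)) next
    for (g2 in cand)
      rows[[length(rows) + 1L]] <- .pair_row(g1, g2, sets1[[g1]], sets2[[g2]])
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$gene1_id, out$gene2_id), , drop = FALSE] |>
    `rownames<-`(NULL)
}

#' All-pairs reference implementation of gene pairing
#'
#' Scans every cross-annotation gene pair and tests the sharing condition
#' directly. Quadratic in the number of genes; intended as the independent
#' oracle against which the indexed [pair_genes()] is verified.
#'
#' @inheritParams pair_genes
#' @return Same shape as [pair_genes()].
#' @export
pair_genes_bruteforce <- function(t1, t2, pair_on = c("boundary", "junction"),
                                  ignore_strand = FALSE) {
  pair_on <- match.arg(pair_on)
  field <- if (pair_on == "boundary") "boundaries" else "junctions"
  sets1 <- .gene_sets(t1, ignore_strand)
  sets2 <- .gene_sets(t2, ignore_strand)
  rows <- list()
  for (g1 in names(sets1)) for (g2 in names(sets2)) {
    if (length(intersect(sets1[[g1]][[field]], sets2[[g2]][[field]])) >= 1L)
      rows[[length(rows) + 1L]] <- .pair_row(g1, g2, sets1[[g1]], sets2[[g2]])
  }
  if (!length(rows))
    return(data.frame(gene1_id = character(), gene2_id = character(),
                      j_boundary = numeric(), j_junction = numeric(),
                      j_chain = numeric(), shared_boundary_count = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$gene1_id, out$gene2_id), , drop = FALSE] |>
    `rownames<-`(NULL)
}
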