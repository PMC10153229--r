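# In-memory transcript/gene/annotation model and extraction of the three
# structural sets of a transcript: intron-exon boundaries B(t), splice
# junctions J(t) and the intron chain C(t), with their unions over genes and
# whole annotations. All coordinates are 0-based half-open; GTF's 1-based
# closed convention is converted exactly once at I/O time.

#' Construct a transcript model
#'
#' A transcript is an ordered set of exons on one chromosome and strand, with
#' an optional predicted abundance (e.g. TPM/FPKM/cov from an assembler) and an
#' optional biotype label (e.g. Ensembl's `transcript_biotype`).
#'
#' Exons use 0-based half-open coordinates and must be non-overlapping with a
#' gap of at least one base between consecutive exons; each gap is an intron.
#' Exons supplied out of order are sorted by start. A zero-length gap between
#' exons is a validation error unless `merge_adjacent = TRUE`, in which case
#' the two exons are merged (repair mode for sloppy upstream GTFs).
#'
#' @param transcript_id,gene_id Character scalars identifying the transcript
#'   and its gene.
#' @param chrom Chromosome name.
#' @param strand One of `"+"`, `"-"`, `"."`.
#' @param exons Two-column matrix (or data frame) of exon `start`, `end`
#'   pairs, 0-based half-open.
#' @param abundance Non-negative numeric abundance, or `NA` when unknown
#'   (reference annotations legitimately lack abundances).
#' @param biotype Biotype label or `NA`.
#' @param attributes Named character vector of original GTF attributes,
#'   preserved verbatim through I/O round trips.
#' @param merge_adjacent Merge zero-gap adjacent exons instead of erroring.
#' @return An object of class `"transcript_model"`.
#' @examples
#' t <- transcript_model("T1", "G1", "chr1", "+",
#'                       rbind(c(100, 200), c(300, 400)))
#' introns_of(t)
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand = ".",
                             exons, abundance = NA_real_,
                             biotype = NA_character_,
                             attributes = character(),
                             merge_adjacent = FALSE) {
  stopifnot(is.character(transcript_id), length(transcript_id) == 1L,
            nzchar(transcript_id),
            is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id),
            is.character(chrom), length(chrom) == 1L,
            strand %in% c("+", "-", "."))
  exons <- .validate_exons(exons, merge_adjacent = merge_adjacent,
                           id = transcript_id)
  abundance <- as.numeric(abundance)
  if (!is.na(abundance) && abundance < 0)
    stop("abundance of '", transcript_id, "' must be non-negative")
  structure(list(transcript_id = transcript_id,
                 gene_id = gene_id,
                 chrom = chrom,
                 strand = strand,
                 exons = exons,
                 abundance = abundance,
                 biotype = as.character(biotype),
                 attributes = attributes),
            class = "transcript_model")
}

# Exon list validation: integer storage, sorted by start, start < end,
# start >= 0, gaps >= 1 base (or merged on request).
.validate_exons <- function(exons, merge_adjacent = FALSE, id = "?") {
  if (is.data.frame(exons)) exons <- as.matrix(exons[, 1:2])
  if (is.null(dim(exons))) exons <- matrix(exons, ncol = 2L, byrow = TRUE)
  if (ncol(exons) != 2L || nrow(exons) < 1L)
    stop("transcript '", id, "': exons must be a non-empty 2-column matrix")
  storage.mode(exons) <- "integer"
  if (anyNA(exons))
    stop("transcript '", id, "': non-integer exon coordinates")
  colnames(exons) <- c("start", "end")
  exons <- exons[order(exons[, 1L], exons[, 2L]), , drop = FALSE]
  if (any(exons[, 1L] < 0L))
    stop("transcript '", id, "': negative exon start")
  if (any(exons[, 2L] <= exons[, 1L]))
    stop("transcript '", id, "': exon end must exceed start (half-open)")
  n <- nrow(exons)
  if (n > 1L) {
    gap <- exons[-1L, 1L] - exons[-n, 2L]
    if (any(gap < 0L))
      stop("transcript '", id, "': overlapping exons")
    if (any(gap == 0L)) {
      if (!merge_adjacent)
        stop("transcript '", id, "': adjacent exons with zero gap ",
             "(use merge_adjacent = TRUE to repair)")
      run <- cumsum(c(TRUE, gap > 0L))  # exons in one run are back-to-back
      exons <- cbind(start = as.integer(tapply(exons[, 1L], run, min)),
                     end = as.integer(tapply(exons[, 2L], run, max)))
    }
  }
  rownames(exons) <- NULL
  exons
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript %s (gene %s) %s:%s %d exon(s) [%d, %d)%s%s>\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand, nrow(x$exons),
              x$exons[1L, 1L], x$exons[nrow(x$exons), 2L],
              if (is.na(x$abundance)) "" else sprintf(" abundance=%g", x$abundance),
              if (is.na(x$biotype)) "" else paste0(" ", x$biotype)))
  invisible(x)
}

#' Construct a gene model
#'
#' @param gene_id Gene identifier; all transcripts must carry it.
#' @param transcripts List of [transcript_model()] objects.
#' @return An object of class `"gene_model"`.
#' @export
gene_model <- function(gene_id, transcripts) {
  stopifnot(length(transcripts) >= 1L)
  ok <- vapply(transcripts, function(t)
    inherits(t, "transcript_model") && identical(t$gene_id, gene_id), NA)
  if (!all(ok))
    stop("all transcripts must be transcript_model objects with gene_id '",
         gene_id, "'")
  names(transcripts) <- vapply(transcripts, `[[`, "", "transcript_id")
  structure(list(gene_id = gene_id, transcripts = transcripts),
            class = "gene_model")
}

#' Construct an annotation set
#'
#' The top-level container for an annotation or an assembly: an indexed
#' collection of transcripts grouped into genes by their `gene_id`.
#'
#' @param transcripts List of [transcript_model()] objects with unique
#'   transcript ids.
#' @return An object of class `"annotation_set"` with elements `transcripts`
#'   (named list) and `genes` (gene_id -> character vector of transcript ids).
#' @export
annotation_set <- function(transcripts = list()) {
  if (length(transcripts)) {
    ok <- vapply(transcripts, inherits, NA, "transcript_model")
    if (!all(ok)) stop("all elements must be transcript_model objects")
    ids <- vapply(transcripts, `[[`, "", "transcript_id")
    if (anyDuplicated(ids))
      stop("duplicate transcript ids: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    names(transcripts) <- ids
    gids <- vapply(transcripts, `[[`, "", "gene_id")
    genes <- split(ids, factor(gids, levels = unique(gids)))
  } else {
    transcripts <- structure(list(), names = character())
    genes <- structure(list(), names = character())
  }
  structure(list(transcripts = transcripts, genes = genes),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set: %d transcript(s) in %d gene(s)>\n",
              length(x$transcripts), length(x$genes)))
  invisible(x)
}

#' @rdname annotation_set
#' @param x An `annotation_set`.
#' @export
n_transcripts <- function(x) length(x$transcripts)

#' @rdname annotation_set
#' @export
transcript_ids <- function(x) names(x$transcripts)

#' @rdname annotation_set
#' @export
gene_ids <- function(x) names(x$genes)

#' @rdname annotation_set
#' @param gene_id Gene to extract.
#' @export
gene_of <- function(x, gene_id) {
  ids <- x$genes[[gene_id]]
  if (is.null(ids)) stop("unknown gene '", gene_id, "'")
  gene_model(gene_id, x$transcripts[ids])
}

# Subset an annotation_set to the given transcript ids, preserving order.
.subset_annotation <- function(x, ids) {
  annotation_set(x$transcripts[names(x$transcripts) %in% ids])
}

#' Introns of a transcript
#'
#' Each gap between consecutive exons is an intron, reported as a junction
#' `(donor, acceptor)` in 0-based half-open coordinates: the donor is the end
#' of the upstream exon, the acceptor the start of the downstream exon
#' ("upstream"/"downstream" in genomic, not transcriptional, order).
#'
#' @param t A [transcript_model()].
#' @return Integer matrix with columns `donor`, `acceptor`; zero rows for a
#'   single-exon transcript.
#' @export
introns_of <- function(t) {
  stopifnot(inherits(t, "transcript_model"))
  n <- nrow(t$exons)
  if (n < 2L)
    return(matrix(integer(), 0L, 2L, dimnames = list(NULL, c("donor", "acceptor"))))
  cbind(donor = t$exons[-n, 2L], acceptor = t$exons[-1L, 1L])
}

#' Intron-exon boundaries of a transcript
#'
#' The set B(t): every position where an exon meets an intron, i.e. the donor
#' and acceptor of every intron. Transcript start and end are *not*
#' boundaries, so a single-exon transcript has none and
#' `length(boundaries_of(t)) == 2 * nrow(introns_of(t))` always holds.
#'
#' @inheritParams introns_of
#' @return Sorted integer vector of boundary positions on `t$chrom`/`t$strand`.
#' @export
boundaries_of <- function(t) {
  ij <- introns_of(t)
  sort(as.integer(ij))
}

#' Intron chain of a transcript
#'
#' The chain C(t): the ordered tuple of all junctions of a multi-exon
#' transcript. It ignores the outer extent of the terminal exons, so two
#' transcripts differing only in their first-exon start or last-exon end have
#' identical chains — the chain is the unit of transcript identity used for
#' matching. Single-exon transcripts have no chain.
#'
#' @inheritParams introns_of
#' @return An object of class `"intron_chain"` (chrom, strand, junction
#'   matrix), or `NULL` for a single-exon transcript.
#' @export
chain_of <- function(t) {
  ij <- introns_of(t)
  if (nrow(ij) == 0L) return(NULL)
  structure(list(chrom = t$chrom, strand = t$strand, junctions = ij),
            class = "intron_chain")
}

#' @export
print.intron_chain <- function(x, ...) {
  cat(sprintf("<intron_chain %s:%s %s>\n", x$chrom, x$strand,
              paste(sprintf("%d-%d", x$junctions[, 1L], x$junctions[, 2L]),
                    collapse = "|")))
  invisible(x)
}

# --- string keys -------------------------------------------------------------
# Structural elements are compared as strings carrying (chrom, strand,
# coordinates) so whole-genome set algebra needs no per-chromosome
# bookkeeping. Features on strand "." only ever equal other "." features;
# ignore_strand collapses all strands to "*".

.strand_key <- function(strand, ignore_strand) if (ignore_strand) "*" else strand

.tx_structure_keys <- function(t, ignore_strand = FALSE) {
  ij <- introns_of(t)
  if (nrow(ij) == 0L)
    return(list(boundaries = character(), junctions = character(),
                chains = character()))
  pre <- paste0(t$chrom, ":", .strand_key(t$strand, ignore_strand), ":")
  jn <- paste0(ij[, 1L], "-", ij[, 2L])
  list(boundaries = paste0(pre, unique(as.integer(ij))),
       junctions = paste0(pre, jn),
       chains = paste0(pre, paste(jn, collapse = "|")))
}

#' Structural sets of a transcript, gene or annotation
#'
#' Computes the boundary, junction and intron-chain sets — B, J and C — of the
#' given scope. For a gene the sets are unions over its transcripts; for an
#' annotation, unions over all genes. Duplicates collapse under union, and
#' single-exon transcripts contribute nothing (all three definitions are
#' intron-based).
#'
#' Elements are encoded as strings keyed by chromosome, strand and
#' coordinates; set `ignore_strand = TRUE` to collapse strands, e.g. when one
#' of two inputs is unstranded.
#'
#' @param x A `transcript_model`, `gene_model` or `annotation_set`.
#' @param ignore_strand Drop strand from element identity.
#' @return Object of class `"structure_sets"`: a list with character-vector
#'   elements `boundaries`, `junctions`, `chains`.
#' @export
structure_sets <- function(x, ignore_strand = FALSE) {
  UseMethod("structure_sets")
}

#' @export
structure_sets.transcript_model <- function(x, ignore_strand = FALSE) {
  structure(.tx_structure_keys(x, ignore_strand), class = "structure_sets")
}

.union_structure_keys <- function(txs, ignore_strand) {
  parts <- lapply(txs, .tx_structure_keys, ignore_strand = ignore_strand)
  structure(list(
    boundaries = unique(unlist(lapply(parts, `[[`, "boundaries"), use.names = FALSE)),
    junctions = unique(unlist(lapply(parts, `[[`, "junctions"), use.names = FALSE)),
    chains = unique(unlist(lapply(parts, `[[`, "chains"), use.names = FALSE))),
    class = "structure_sets")
}

#' @export
structure_sets.gene_model <- function(x, ignore_strand = FALSE) {
  .union_structure_keys(x$transcripts, ignore_strand)
}

#' @export
structure_sets.annotation_set <- function(x, ignore_strand = FALSE) {
  .union_structure_keys(x$transcripts, ignore_strand)
}

#' @export
print.structure_sets <- function(x, ...) {
  cat(sprintf("<structure_sets: %d boundaries, %d junctions, %d chains>\n",
              length(x$boundaries), length(x$junctions), length(x$chains)))
  invisible(x)
}
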