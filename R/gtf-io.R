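# GTF reading and writing across annotation and assembler dialects.
#
# Ensembl, RefSeq and CHM13 annotations and StringTie2/Scallop2 assemblies all
# emit 9-column GTF but disagree on the column-9 attribute vocabulary
# (biotype keys, abundance keys, quoting). A dialect configuration names the
# keys to look for, in order of precedence. Coordinates are converted between
# GTF's 1-based closed convention and the internal 0-based half-open
# convention exactly once, here.

#' GTF dialect configuration
#'
#' @param feature_types_kept Feature types (column 3) that carry exon
#'   structure; `"exon"` for every dialect this package targets.
#' @param transcript_id_key,gene_id_key Attribute keys carrying transcript and
#'   gene identifiers; the first present key wins.
#' @param biotype_keys Attribute keys tried, in order, for the transcript
#'   biotype. `transcript_biotype` is Ensembl's; `gbkey` covers RefSeq-style
#'   files.
#' @param abundance_keys Attribute keys tried, in order, for the predicted
#'   abundance. StringTie2 and Scallop2 both write `cov`, `FPKM` and `TPM`;
#'   the default precedence is TPM, then FPKM, then cov.
#' @return A list of class `"gtf_dialect"`.
#' @export
gtf_dialect <- function(feature_types_kept = "exon",
                        transcript_id_key = "transcript_id",
                        gene_id_key = "gene_id",
                        biotype_keys = c("transcript_biotype", "gbkey"),
                        abundance_keys = c("TPM", "FPKM", "cov")) {
  stopifnot(length(transcript_id_key) >= 1L, nzchar(transcript_id_key),
            length(gene_id_key) >= 1L, nzchar(gene_id_key))
  structure(list(feature_types_kept = feature_types_kept,
                 transcript_id_key = transcript_id_key,
                 gene_id_key = gene_id_key,
                 biotype_keys = biotype_keys,
                 abundance_keys = abundance_keys),
            class = "gtf_dialect")
}

#' Parse a GTF column-9 attribute field
#'
#' Best-effort parser for `key "value";` pairs. Tolerates a missing trailing
#' semicolon, unquoted numeric values (`cov 5.2;`, a RefSeq/GFF-ish quirk) and
#' stray whitespace. Duplicate keys keep the first occurrence.
#'
#' @param field Attribute string (column 9 of one GTF row).
#' @return Named character vector; empty for an empty field.
#' @examples
#' parse_gtf_attributes('gene_id "G1"; transcript_id "T1";')
#' parse_gtf_attributes("cov 5.2")
#' @export
parse_gtf_attributes <- function(field) {
  stopifnot(is.character(field), length(field) == 1L)
  field <- trimws(field)
  if (!nzchar(field) || field == ".") return(structure(character(), names = character()))
  m <- gregexpr('([A-Za-z_][A-Za-z0-9_.:-]*)\\s+("[^"]*"|[^;]+?)\\s*(;|$)',
                field, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(structure(character(), names = character()))
  pieces <- regmatches(field, list(m))[[1L]]
  keys <- sub('^([A-Za-z_][A-Za-z0-9_.:-]*)\\s+.*$', "\\1", pieces, perl = TRUE)
  vals <- sub('^[A-Za-z_][A-Za-z0-9_.:-]*\\s+("?)(.*?)\\1\\s*;?\\s*$', "\\2",
              pieces, perl = TRUE)
  keep <- !duplicated(keys)
  structure(vals[keep], names = keys[keep])
}

.first_present <- function(attrs, keys) {
  for (k in keys) if (!is.na(v <- attrs[k][[1L]]) && nzchar(v)) return(v)
  NA_character_
}

#' Read a GTF file into an annotation set
#'
#' Builds transcripts from `exon` features grouped by transcript id, converts
#' 1-based closed coordinates to the internal 0-based half-open convention,
#' and picks up per-transcript abundance and biotype from `transcript`
#' feature rows (falling back to the exon rows of the same transcript).
#' Malformed lines, and transcripts whose exons span multiple chromosomes or
#' strands, are skipped with a warning; counts are attached as attributes
#' `n_malformed_lines` and `n_rejected_transcripts`.
#'
#' @param path Path to a tab-separated 9-column GTF file.
#' @param dialect A [gtf_dialect()].
#' @param merge_adjacent Repair zero-gap adjacent exons by merging them
#'   instead of rejecting the transcript.
#' @return An [annotation_set()].
#' @export
read_gtf <- function(path, dialect = gtf_dialect(), merge_adjacent = FALSE) {
  if (!file.exists(path)) stop("cannot read GTF file '", path, "'")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  n_malformed <- 0L
  exon_rows <- list()
  tx_attrs <- list()     # transcript-feature attributes per transcript id
  for (line in lines) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(f) != 9L) { n_malformed <- n_malformed + 1L; next }
    feat <- f[3L]
    is_exon <- feat %in% dialect$feature_types_kept
    if (!is_exon && feat != "transcript") next
    start <- suppressWarnings(as.integer(f[4L]))
    end <- suppressWarnings(as.integer(f[5L]))
    if (is.na(start) || is.na(end)) { n_malformed <- n_malformed + 1L; next }
    attrs <- parse_gtf_attributes(f[9L])
    tid <- .first_present(attrs, dialect$transcript_id_key)
    if (is.na(tid)) { n_malformed <- n_malformed + 1L; next }
    if (is_exon) {
      exon_rows[[length(exon_rows) + 1L]] <-
        list(tid = tid, chrom = f[1L], strand = f[7L],
             start = start - 1L, end = end, attrs = attrs)
    } else if (is.null(tx_attrs[[tid]])) {
      tx_attrs[[tid]] <- attrs
    }
  }
  if (!length(exon_rows)) {
    ann <- annotation_set()
    attr(ann, "n_malformed_lines") <- n_malformed
    attr(ann, "n_rejected_transcripts") <- 0L
    return(ann)
  }
  tids <- vapply(exon_rows, `[[`, "", "tid")
  by_tx <- split(exon_rows, factor(tids, levels = unique(tids)))
  txs <- list()
  n_rejected <- 0L
  for (tid in names(by_tx)) {
    rows <- by_tx[[tid]]
    chrom <- unique(vapply(rows, `[[`, "", "chrom"))
    strand <- unique(vapply(rows, `[[`, "", "strand"))
    if (length(chrom) != 1L || length(strand) != 1L) {
      warning("rejecting transcript '", tid,
              "': exons span multiple chromosomes or strands", call. = FALSE)
      n_rejected <- n_rejected + 1L
      next
    }
    if (!strand %in% c("+", "-", ".")) strand <- "."
    exons <- cbind(vapply(rows, `[[`, 0L, "start"),
                   vapply(rows, `[[`, 0L, "end"))
    attrs <- tx_attrs[[tid]]
    if (is.null(attrs)) attrs <- rows[[1L]]$attrs
    gid <- .first_present(attrs, dialect$gene_id_key)
    if (is.na(gid)) gid <- .first_present(rows[[1L]]$attrs, dialect$gene_id_key)
    if (is.na(gid)) gid <- tid  # last resort: orphan transcript is its own gene
    # abundance/biotype: transcript feature first, exon feature fallback
    ab <- .first_present(attrs, dialect$abundance_keys)
    if (is.na(ab)) ab <- .first_present(rows[[1L]]$attrs, dialect$abundance_keys)
    bt <- .first_present(attrs, dialect$biotype_keys)
    if (is.na(bt)) bt <- .first_present(rows[[1L]]$attrs, dialect$biotype_keys)
    tx <- tryCatch(
      transcript_model(tid, gid, chrom, strand, exons,
                       abundance = if (is.na(ab)) NA_real_ else as.numeric(ab),
                       biotype = bt, attributes = attrs,
                       merge_adjacent = merge_adjacent),
      error = function(e) {
        warning("rejecting transcript '", tid, "': ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(tx)) { n_rejected <- n_rejected + 1L; next }
    txs[[tid]] <- tx
  }
  ann <- annotation_set(txs)
  attr(ann, "n_malformed_lines") <- n_malformed
  attr(ann, "n_rejected_transcripts") <- n_rejected
  ann
}

.format_attrs <- function(attrs) {
  if (!length(attrs)) return("")
  paste0(paste0(names(attrs), ' "', attrs, '";', collapse = " "))
}

#' Write an annotation set as GTF
#'
#' Emits one `transcript` row plus one `exon` row per exon, in 1-based closed
#' coordinates, sorted by (chrom, start, transcript id). Original attributes
#' are preserved; `gene_id` and `transcript_id` are always emitted first, and
#' an abundance (`TPM`) or biotype (`transcript_biotype`) attribute is added
#' when the model carries one that the original attributes do not, so that
#' `read_gtf(write_gtf(x))` reproduces coordinates, ids, abundances and
#' biotypes.
#'
#' @param x An [annotation_set()].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_gtf <- function(x, path) {
  stopifnot(inherits(x, "annotation_set"))
  txs <- x$transcripts
  out <- character()
  if (length(txs)) {
    ord <- order(vapply(txs, `[[`, "", "chrom"),
                 vapply(txs, function(t) t$exons[1L, 1L], 0L),
                 names(txs))
    for (t in txs[ord]) {
      attrs <- t$attributes
      attrs <- attrs[!names(attrs) %in% c("gene_id", "transcript_id")]
      base <- c(gene_id = t$gene_id, transcript_id = t$transcript_id)
      if (!is.na(t$abundance) &&
          !any(c("TPM", "FPKM", "cov") %in% names(attrs)))
        attrs <- c(attrs, TPM = sprintf("%.17g", t$abundance))
      if (!is.na(t$biotype) &&
          !any(c("transcript_biotype", "gbkey") %in% names(attrs)))
        attrs <- c(attrs, transcript_biotype = t$biotype)
      attrs <- c(base, attrs)
      span <- c(t$exons[1L, 1L] + 1L, t$exons[nrow(t$exons), 2L])
      out <- c(out,
               paste(t$chrom, "introntools", "transcript", span[1L], span[2L],
                     ".", t$strand, ".", .format_attrs(attrs), sep = "\t"),
               paste(t$chrom, "introntools", "exon",
                     t$exons[, 1L] + 1L, t$exons[, 2L],
                     ".", t$strand, ".", .format_attrs(attrs), sep = "\t"))
    }
  }
  writeLines(out, path)
  invisible(path)
}
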