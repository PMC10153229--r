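# Detection of transcripts with (partial) intron retentions in an assembly.
#
# A transcript t is flagged when some other transcript r of the same assembly
# has sufficiently high relative abundance (p(r)/p(t) strictly above a
# threshold, 0.5 by default) and one of three geometric criteria holds:
#   1. the first exon of t spans an intron of r and the exon following it,
#   2. the last exon of t spans an exon of r and the intron following it,
#   3. some exon of t fully covers some intron of r.
# Criteria 1 and 2 capture partial retention at a transcript end; criterion 3
# captures full retention. "First"/"last" mean genomically leftmost/rightmost,
# so the two partial criteria mirror each other under strand flip.

#' Intron-retention detection parameters
#'
#' @param ratio_threshold Abundance-ratio gate: a reference transcript `r`
#'   qualifies only when `p(r)/p(t)` is *strictly* above this value. Default
#'   0.5.
#' @param require_same_strand Only consider reference transcripts on the same
#'   strand as `t` (intron retention is a splicing event within one locus).
#' @param min_overlap_bases Minimum overlap, in bases, required on each side
#'   of the crossed boundary for the "spans" tests of criteria 1 and 2.
#'   Default 1 (the weakest reading); raise it for stricter spanning.
#' @param ignore_abundance Disable the abundance gate entirely: every ratio
#'   test passes and reported ratios are `NA`. Required when the assembly
#'   carries no abundances.
#' @return A list of class `"ir_params"`.
#' @export
ir_params <- function(ratio_threshold = 0.5, require_same_strand = TRUE,
                      min_overlap_bases = 1L, ignore_abundance = FALSE) {
  if (!is.numeric(ratio_threshold) || length(ratio_threshold) != 1L ||
      is.na(ratio_threshold) || ratio_threshold < 0)
    stop("ratio_threshold must be a single non-negative number")
  min_overlap_bases <- as.integer(min_overlap_bases)
  if (is.na(min_overlap_bases) || min_overlap_bases < 1L)
    stop("min_overlap_bases must be a positive integer")
  structure(list(ratio_threshold = as.numeric(ratio_threshold),
                 require_same_strand = isTRUE(require_same_strand),
                 min_overlap_bases = min_overlap_bases,
                 ignore_abundance = isTRUE(ignore_abundance)),
            class = "ir_params")
}

#' Candidate reference transcripts for intron-retention testing
#'
#' Returns every transcript `r != t` of the assembly on the same chromosome
#' (and strand, when required) whose genomic span overlaps that of `t` and
#' whose abundance passes the ratio gate `p(r)/p(t) > ratio_threshold`
#' (strict). With `ignore_abundance` the ratio gate always passes.
#'
#' @param t A [transcript_model()] with positive abundance (unless
#'   `ignore_abundance`).
#' @param assembly The [annotation_set()] containing `t` and its potential
#'   references.
#' @param params An [ir_params()] object.
#' @return A list of `transcript_model` objects.
#' @export
candidate_references <- function(t, assembly, params = ir_params()) {
  stopifnot(inherits(t, "transcript_model"), inherits(assembly, "annotation_set"))
  if (!params$ignore_abundance) {
    if (is.na(t$abundance))
      stop("transcript '", t$transcript_id, "' has no abundance; ",
           "supply abundances or set ignore_abundance = TRUE")
    if (t$abundance <= 0)
      stop("transcript '", t$transcript_id, "' has non-positive abundance")
  }
  t_span <- c(t$exons[1L, 1L], t$exons[nrow(t$exons), 2L])
  keep <- vapply(assembly$transcripts, function(r) {
    if (identical(r$transcript_id, t$transcript_id)) return(FALSE)
    if (!identical(r$chrom, t$chrom)) return(FALSE)
    if (params$require_same_strand && !identical(r$strand, t$strand))
      return(FALSE)
    r_span <- c(r$exons[1L, 1L], r$exons[nrow(r$exons), 2L])
    if (max(t_span[1L], r_span[1L]) >= min(t_span[2L], r_span[2L]))
      return(FALSE)
    if (params$ignore_abundance) return(TRUE)
    if (is.na(r$abundance))
      stop("transcript '", r$transcript_id, "' has no abundance; ",
           "supply abundances or set ignore_abundance = TRUE")
    r$abundance / t$abundance > params$ratio_threshold
  }, NA)
  unname(assembly$transcripts[keep])
}

# overlap length of [s1,e1) and [s2,e2)
.ovl <- function(s1, e1, s2, e2) pmin(e1, e2) - pmax(s1, s2)

#' Partial intron retention at the transcript start (criterion 1)
#'
#' `TRUE` iff some intron `(a, b)` of `r` is such that the genomically first
#' exon of `t` overlaps the intron by at least `min_overlap` bases *and*
#' overlaps the exon of `r` immediately following the intron by at least
#' `min_overlap` bases — i.e. the first exon of `t` crosses the acceptor `b`.
#' Pure geometry: chromosome, strand and abundance gates live in
#' [candidate_references()].
#'
#' @param t,r [transcript_model()] objects (the flag candidate and the
#'   reference).
#' @param min_overlap Minimum per-side overlap in bases.
#' @return Logical scalar; `FALSE` whenever `r` is single-exon.
#' @export
check_criterion1 <- function(t, r, min_overlap = 1L) {
  ri <- introns_of(r)
  if (nrow(ri) == 0L) return(FALSE)
  f <- t$exons[1L, ]
  nxt <- r$exons[-1L, , drop = FALSE]  # exon following intron i
  any(.ovl(f[1L], f[2L], ri[, 1L], ri[, 2L]) >= min_overlap &
      .ovl(f[1L], f[2L], nxt[, 1L], nxt[, 2L]) >= min_overlap)
}

#' Partial intron retention at the transcript end (criterion 2)
#'
#' Mirror image of [check_criterion1()]: `TRUE` iff the genomically last exon
#' of `t` overlaps some exon of `r` and the intron immediately following it,
#' each by at least `min_overlap` bases — the last exon crosses the donor.
#'
#' @inheritParams check_criterion1
#' @return Logical scalar.
#' @export
check_criterion2 <- function(t, r, min_overlap = 1L) {
  ri <- introns_of(r)
  if (nrow(ri) == 0L) return(FALSE)
  l <- t$exons[nrow(t$exons), ]
  prv <- r$exons[-nrow(r$exons), , drop = FALSE]  # exon preceding intron i
  any(.ovl(l[1L], l[2L], prv[, 1L], prv[, 2L]) >= min_overlap &
      .ovl(l[1L], l[2L], ri[, 1L], ri[, 2L]) >= min_overlap)
}

#' Full intron retention (criterion 3)
#'
#' `TRUE` iff some exon `[s, e)` of `t` fully covers some intron `[a, b)` of
#' `r`, i.e. `s <= a` and `b <= e` (equality counts as covered).
#'
#' @inheritParams check_criterion1
#' @return Logical scalar.
#' @export
check_criterion3 <- function(t, r, min_overlap = 1L) {
  ri <- introns_of(r)
  if (nrow(ri) == 0L) return(FALSE)
  ex <- t$exons
  for (i in seq_len(nrow(ri)))
    if (any(ex[, 1L] <= ri[i, 1L] & ri[i, 2L] <= ex[, 2L])) return(TRUE)
  FALSE
}

.empty_calls <- function() {
  structure(data.frame(t_id = character(), r_id = character(),
                       criterion = integer(), ratio = numeric(),
                       stringsAsFactors = FALSE),
            class = c("ir_calls", "data.frame"))
}

#' Detect intron-retention events in an assembly
#'
#' For every ordered transcript pair `(t, r)` with `r` among the candidate
#' references of `t`, emits one call per satisfied criterion. A transcript is
#' "IR-flagged" iff it receives at least one call; the same `t` may satisfy
#' several criteria against one `r`, or criteria against several `r`, and
#' every call is reported. Output is deterministically ordered by
#' `(t_id, r_id, criterion)`.
#'
#' Transcripts with zero abundance cannot anchor a ratio and are skipped with
#' a warning (they may still serve as references, where a zero numerator
#' simply fails the gate).
#'
#' @param assembly An [annotation_set()]; transcripts need abundances unless
#'   `params$ignore_abundance`.
#' @param params An [ir_params()] object.
#' @return A data frame of class `"ir_calls"` with columns `t_id`, `r_id`,
#'   `criterion` (1, 2 or 3) and `ratio` (`p(r)/p(t)`; `NA` when the
#'   abundance gate is disabled).
#' @examples
#' calls <- detect_ir(toy_ir_assembly())
#' unique(calls$t_id)
#' @export
detect_ir <- function(assembly, params = ir_params()) {
  stopifnot(inherits(assembly, "annotation_set"))
  txs <- assembly$transcripts
  if (length(txs) < 2L) return(.empty_calls())
  rows <- vector("list", 0L)
  for (t in txs) {
    if (!params$ignore_abundance) {
      if (is.na(t$abundance))
        stop("transcript '", t$transcript_id, "' has no abundance; ",
             "supply abundances or set ignore_abundance = TRUE")
      if (t$abundance <= 0) {
        warning("skipping transcript '", t$transcript_id,
                "' with zero abundance", call. = FALSE)
        next
      }
    }
    for (r in candidate_references(t, assembly, params)) {
      hit <- c(check_criterion1(t, r, params$min_overlap_bases),
               check_criterion2(t, r, params$min_overlap_bases),
               check_criterion3(t, r, params$min_overlap_bases))
      if (any(hit)) {
        ratio <- if (params$ignore_abundance) NA_real_
                 else r$abundance / t$abundance
        rows[[length(rows) + 1L]] <-
          data.frame(t_id = t$transcript_id, r_id = r$transcript_id,
                     criterion = which(hit), ratio = ratio,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(.empty_calls())
  out <- do.call(rbind, rows)
  out <- out[order(out$t_id, out$r_id, out$criterion), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ir_calls", "data.frame")
  out
}

#' Split an assembly by its intron-retention calls
#'
#' Partitions the assembly into the transcripts flagged by at least one call
#' (`removed`) and the rest (`kept`). The two parts are disjoint, exhaustive,
#' and preserve attributes and abundances, so `kept` is the
#' intron-retention-filtered assembly and `removed` the extracted
#' retained-intron transcripts.
#'
#' @param assembly The [annotation_set()] the calls were produced from.
#' @param calls An `ir_calls` data frame from [detect_ir()].
#' @return A list with `annotation_set` elements `kept` and `removed`.
#' @export
split_assembly <- function(assembly, calls) {
  stopifnot(inherits(assembly, "annotation_set"), is.data.frame(calls))
  flagged <- unique(calls$t_id)
  unknown <- setdiff(flagged, names(assembly$transcripts))
  if (length(unknown))
    stop("calls reference transcripts absent from the assembly: ",
         paste(unknown, collapse = ", "))
  ids <- names(assembly$transcripts)
  list(kept = .subset_annotation(assembly, setdiff(ids, flagged)),
       removed = .subset_annotation(assembly, flagged))
}
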