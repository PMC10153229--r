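# Assembly-vs-annotation evaluation with transcript-level matching:
# a multi-exon assembled transcript matches when its intron chain exactly
# equals that of an annotated transcript; a single-exon one matches on
# reciprocal overlap with a single-exon annotated transcript. Precision is
# #matching / #assembled; #matching serves as the recall proxy when the
# annotation stands in for the (unknown) expressed truth.

# Matching index over a reference annotation: chain key -> representative
# transcript id (first by chrom, start, id), plus a table of single-exon
# reference transcripts in the same deterministic order.
.ref_match_index <- function(ref, ignore_strand = FALSE) {
  txs <- ref$transcripts
  if (!length(txs))
    return(list(chains = structure(character(), names = character()),
                single = data.frame(id = character(), chrom = character(),
                                    strand = character(), start = integer(),
                                    end = integer(), stringsAsFactors = FALSE)))
  ord <- order(vapply(txs, `[[`, "", "chrom"),
               vapply(txs, function(t) t$exons[1L, 1L], 0L),
               names(txs))
  txs <- txs[ord]
  nex <- vapply(txs, function(t) nrow(t$exons), 0L)
  chains <- character()
  if (any(nex >= 2L)) {
    multi <- txs[nex >= 2L]
    keys <- vapply(multi, function(t)
      .tx_structure_keys(t, ignore_strand)$chains, "")
    chains <- structure(names(multi), names = keys)
    chains <- chains[!duplicated(keys)]
  }
  single <- txs[nex == 1L]
  single_df <- data.frame(
    id = names(single),
    chrom = vapply(single, `[[`, "", "chrom"),
    strand = vapply(single, `[[`, "", "strand"),
    start = vapply(single, function(t) t$exons[1L, 1L], 0L),
    end = vapply(single, function(t) t$exons[1L, 2L], 0L),
    stringsAsFactors = FALSE, row.names = NULL)
  list(chains = chains, single = single_df)
}

.match_one <- function(t, index, single_exon_min_overlap, ignore_strand) {
  if (nrow(t$exons) >= 2L) {
    key <- .tx_structure_keys(t, ignore_strand)$chains
    hit <- index$chains[key][[1L]]
    return(if (is.na(hit)) NA_character_ else hit)
  }
  s <- t$exons[1L, 1L]
  e <- t$exons[1L, 2L]
  cand <- index$single
  ok <- cand$chrom == t$chrom &
    (ignore_strand | cand$strand == t$strand)
  if (!any(ok)) return(NA_character_)
  cand <- cand[ok, , drop = FALSE]
  ov <- pmin(e, cand$end) - pmax(s, cand$start)
  good <- ov >= single_exon_min_overlap * (e - s) &
    ov >= single_exon_min_overlap * (cand$end - cand$start)
  if (!any(good)) return(NA_character_)
  cand$id[which(good)[1L]]
}

#' Match one assembled transcript against a reference annotation
#'
#' A multi-exon transcript matches iff some reference transcript has an
#' identical intron chain (same chromosome, strand and full junction tuple);
#' terminal-exon extents are ignored. A single-exon transcript matches iff
#' some single-exon reference transcript overlaps it reciprocally by at least
#' `single_exon_min_overlap` of *both* transcripts' lengths (0.8 by default).
#' Among multiple candidates, the first by (chrom, start, id) order is
#' reported.
#'
#' @param t A [transcript_model()].
#' @param ref The reference [annotation_set()].
#' @param single_exon_min_overlap Reciprocal-overlap fraction for single-exon
#'   matching.
#' @param ignore_strand Match without strand identity.
#' @return The matched reference transcript id, or `NA` if none.
#' @export
match_transcript <- function(t, ref, single_exon_min_overlap = 0.8,
                             ignore_strand = FALSE) {
  stopifnot(inherits(t, "transcript_model"), inherits(ref, "annotation_set"))
  .match_one(t, .ref_match_index(ref, ignore_strand),
             single_exon_min_overlap, ignore_strand)
}

#' Evaluate an assembly against a reference annotation
#'
#' Applies [match_transcript()] to every assembled transcript and reports the
#' number of matching transcripts and the precision
#' `num_matching / num_assembled`. Duplicate chains in the assembly each
#' count separately (the unit is assembled transcripts, not unique chains);
#' `dedup_chains = TRUE` collapses multi-exon duplicates to one
#' representative before counting.
#'
#' @param assembly,ref [annotation_set()] objects.
#' @inheritParams match_transcript
#' @param dedup_chains Count each distinct intron chain at most once.
#' @return A list of class `"match_result"`: `matches` (named character
#'   vector, assembled id -> reference id or `NA`), `num_matching`,
#'   `num_assembled`, `precision` (`NA` for an empty assembly).
#' @export
evaluate_assembly <- function(assembly, ref, single_exon_min_overlap = 0.8,
                              ignore_strand = FALSE, dedup_chains = FALSE) {
  stopifnot(inherits(assembly, "annotation_set"), inherits(ref, "annotation_set"))
  txs <- assembly$transcripts
  if (dedup_chains && length(txs)) {
    keys <- vapply(txs, function(t) {
      k <- .tx_structure_keys(t, ignore_strand)$chains
      if (length(k)) k else paste0("single:", t$transcript_id)
    }, "")
    txs <- txs[!duplicated(keys)]
  }
  index <- .ref_match_index(ref, ignore_strand)
  matches <- vapply(txs, .match_one, "",
                    index = index,
                    single_exon_min_overlap = single_exon_min_overlap,
                    ignore_strand = ignore_strand)
  num_assembled <- length(txs)
  num_matching <- sum(!is.na(matches))
  structure(list(matches = matches,
                 num_matching = num_matching,
                 num_assembled = num_assembled,
                 precision = if (num_assembled == 0L) NA_real_
                             else num_matching / num_assembled),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result: %d/%d matching, precision %s>\n",
              x$num_matching, x$num_assembled,
              if (is.na(x$precision)) "NA" else sprintf("%.4f", x$precision)))
  invisible(x)
}

#' Adjusted precision of the higher-recall assembly
#'
#' When two assemblies disagree in opposite directions on precision and
#' number of matching transcripts, the higher-recall one is trimmed for a
#' like-for-like comparison: its transcripts are removed one at a time in
#' order of increasing predicted abundance (ties broken by transcript id)
#' until its matching count equals `target_matching` — the other assembly's
#' count — and the precision at that point is the adjusted precision.
#' Abundance correlates strongly with assembly correctness, so precision
#' typically rises as recall is given up.
#'
#' @param assembly The higher-recall [annotation_set()]; all transcripts must
#'   carry abundances.
#' @param ref The reference [annotation_set()].
#' @param target_matching Matching count to trim down to; must not exceed the
#'   assembly's current matching count.
#' @inheritParams match_transcript
#' @return A list: `adjusted_precision`, `num_matching` (equals
#'   `target_matching`), `num_remaining`, `removed_ids`.
#' @export
adjusted_precision <- function(assembly, ref, target_matching,
                               single_exon_min_overlap = 0.8,
                               ignore_strand = FALSE) {
  stopifnot(inherits(assembly, "annotation_set"))
  target_matching <- as.integer(target_matching)
  res <- evaluate_assembly(assembly, ref,
                           single_exon_min_overlap = single_exon_min_overlap,
                           ignore_strand = ignore_strand)
  if (target_matching > res$num_matching)
    stop("target_matching (", target_matching,
         ") exceeds current matching count (", res$num_matching, ")")
  ab <- vapply(assembly$transcripts, `[[`, NA_real_, "abundance")
  if (anyNA(ab))
    stop("adjusted precision requires abundances on all transcripts")
  # removing a transcript never changes whether another one matches, so the
  # removal sweep reduces to walking the abundance order and decrementing
  ord <- order(ab, names(ab))
  ids <- names(ab)[ord]
  is_match <- !is.na(res$matches[ids])
  num_matching <- res$num_matching
  num_remaining <- res$num_assembled
  removed <- character()
  i <- 0L
  while (num_matching > target_matching) {
    i <- i + 1L
    removed <- c(removed, ids[i])
    num_remaining <- num_remaining - 1L
    if (is_match[i]) num_matching <- num_matching - 1L
  }
  stopifnot(num_matching == target_matching)  # removals decrement by 0 or 1
  list(adjusted_precision = if (num_remaining == 0L) NA_real_
                            else num_matching / num_remaining,
       num_matching = num_matching,
       num_remaining = num_remaining,
       removed_ids = removed)
}

.biotype_of <- function(t) {
  if (is.na(t$biotype) || !nzchar(t$biotype)) "unlabeled" else t$biotype
}

#' Biotype cross-tabulation of two annotations
#'
#' For each transcript biotype of the reference, counts its multi-exon
#' transcripts (unique by intron chain) and how many of those chains also
#' occur in `other`. Two transcripts are considered the same when they share
#' the same intron chain. Reference transcripts without a biotype are grouped
#' under `"unlabeled"`.
#'
#' @param ref An [annotation_set()] carrying biotypes.
#' @param other The annotation to look the chains up in.
#' @param ignore_strand Compare chains without strand identity.
#' @return A data frame with columns `biotype`, `n_ref`, `n_matched`,
#'   `percent`, ordered by decreasing `n_ref`.
#' @export
biotype_crosstab <- function(ref, other, ignore_strand = FALSE) {
  stopifnot(inherits(ref, "annotation_set"), inherits(other, "annotation_set"))
  txs <- Filter(function(t) nrow(t$exons) >= 2L, ref$transcripts)
  if (!length(txs))
    return(data.frame(biotype = character(), n_ref = integer(),
                      n_matched = integer(), percent = numeric(),
                      stringsAsFactors = FALSE))
  keys <- vapply(txs, function(t) .tx_structure_keys(t, ignore_strand)$chains, "")
  bts <- vapply(txs, .biotype_of, "")
  dedup <- !duplicated(paste(bts, keys))  # one count per (biotype, chain)
  keys <- keys[dedup]
  bts <- bts[dedup]
  other_chains <- structure_sets(other, ignore_strand = ignore_strand)$chains
  hit <- keys %in% other_chains
  n_ref <- table(bts)
  n_matched <- tapply(hit, bts, sum)[names(n_ref)]
  out <- data.frame(biotype = names(n_ref),
                    n_ref = as.integer(n_ref),
                    n_matched = as.integer(n_matched),
                    stringsAsFactors = FALSE, row.names = NULL)
  out$percent <- 100 * out$n_matched / out$n_ref
  out[order(-out$n_ref, out$biotype), , drop = FALSE] |> `rownames<-`(NULL)
}

#' Matching transcripts stratified by reference biotype
#'
#' Evaluates the assembly against a biotype-carrying reference and counts how
#' many assembled transcripts matched a reference transcript of each biotype.
#'
#' @param assembly An [annotation_set()].
#' @param ref The biotype-carrying reference [annotation_set()].
#' @inheritParams match_transcript
#' @return A data frame with columns `biotype`, `n_matching`, ordered by
#'   decreasing count; zero rows when nothing matches.
#' @export
stratify_matches_by_biotype <- function(assembly, ref,
                                        single_exon_min_overlap = 0.8,
                                        ignore_strand = FALSE) {
  res <- evaluate_assembly(assembly, ref,
                           single_exon_min_overlap = single_exon_min_overlap,
                           ignore_strand = ignore_strand)
  hits <- res$matches[!is.na(res$matches)]
  if (!length(hits))
    return(data.frame(biotype = character(), n_matching = integer(),
                      stringsAsFactors = FALSE))
  bts <- vapply(ref$transcripts[hits], .biotype_of, "")
  tab <- table(bts)
  out <- data.frame(biotype = names(tab), n_matching = as.integer(tab),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$n_matching, out$biotype), , drop = FALSE] |> `rownames<-`(NULL)
}

#' Assembled transcripts annotated in one reference but not another
#'
#' Counts assembled transcripts that match `ref_a` but not `ref_b`,
#' stratified by the biotype of the `ref_a` transcript they match. These are
#' the transcripts one annotation treats as true positives and the other as
#' false positives.
#'
#' @param assembly An [annotation_set()].
#' @param ref_a The biotype-carrying reference whose exclusive matches are
#'   counted.
#' @param ref_b The reference the transcripts must *not* match.
#' @inheritParams match_transcript
#' @return A data frame with columns `biotype`, `n_exclusive`.
#' @export
exclusive_matches <- function(assembly, ref_a, ref_b,
                              single_exon_min_overlap = 0.8,
                              ignore_strand = FALSE) {
  res_a <- evaluate_assembly(assembly, ref_a,
                             single_exon_min_overlap = single_exon_min_overlap,
                             ignore_strand = ignore_strand)
  res_b <- evaluate_assembly(assembly, ref_b,
                             single_exon_min_overlap = single_exon_min_overlap,
                             ignore_strand = ignore_strand)
  excl <- !is.na(res_a$matches) & is.na(res_b$matches)
  hits <- res_a$matches[excl]
  if (!length(hits))
    return(data.frame(biotype = character(), n_exclusive = integer(),
                      stringsAsFactors = FALSE))
  bts <- vapply(ref_a$transcripts[hits], .biotype_of, "")
  tab <- table(bts)
  out <- data.frame(biotype = names(tab), n_exclusive = as.integer(tab),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$n_exclusive, out$biotype), , drop = FALSE] |> `rownames<-`(NULL)
}
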