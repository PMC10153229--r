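# Annotation-level structural similarity: Jaccard indices over the boundary,
# junction and intron-chain sets of two annotations.

#' Jaccard index of two finite sets
#'
#' `|A ∩ B| / |A ∪ B|` over the unique elements of each input. When both sets
#' are empty the index is undefined and `NA` is returned rather than 0 or 1:
#' two annotations with no multi-exon structure have no measurable structural
#' similarity, and a silent 1.0 would fabricate one.
#'
#' @param a,b Character vectors of set elements (one structural level at a
#'   time; see [structure_sets()]).
#' @return A number in `[0, 1]`, or `NA` if both sets are empty.
#' @export
jaccard_index <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  n_union <- length(union(a, b))
  if (n_union == 0L) return(NA_real_)
  length(intersect(a, b)) / n_union
}

#' Structural similarity of two annotations
#'
#' Computes the Jaccard similarity of two annotations at the boundary,
#' junction and intron-chain levels: for each level the element sets are the
#' unions over all transcripts of each annotation, and the similarity is
#' `|intersection| / |union|`. The set cardinalities are reported alongside
#' each value for auditability.
#'
#' @param t1,t2 Two [annotation_set()] objects.
#' @param ignore_strand Compare structural elements without strand identity.
#' @return A data frame with one row per level (`boundary`, `junction`,
#'   `intron_chain`) and columns `n1`, `n2`, `n_shared`, `n_union`, `jaccard`.
#'   A `jaccard` value is `NA` when both sets at that level are empty.
#' @examples
#' pair <- toy_annotation_pair()
#' compare_annotations(pair$t1, pair$t2)
#' @export
compare_annotations <- function(t1, t2, ignore_strand = FALSE) {
  stopifnot(inherits(t1, "annotation_set"), inherits(t2, "annotation_set"))
  s1 <- structure_sets(t1, ignore_strand = ignore_strand)
  s2 <- structure_sets(t2, ignore_strand = ignore_strand)
  level_field <- c(boundary = "boundaries", junction = "junctions",
                   intron_chain = "chains")
  rows <- lapply(names(level_field), function(level) {
    a <- s1[[level_field[[level]]]]
    b <- s2[[level_field[[level]]]]
    data.frame(level = level,
               n1 = length(a), n2 = length(b),
               n_shared = length(intersect(a, b)),
               n_union = length(union(a, b)),
               jaccard = jaccard_index(a, b),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("similarity_report", "data.frame")
  out
}
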