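# Hand-built toy instances pinning the published outcomes of the two
# illustrative examples: a pair of tiny annotations with known Jaccard
# similarities at all three structural levels, and a four-transcript assembly
# in which each of the three intron-retention criteria fires exactly once.

#' Toy annotation pair with known structural similarity
#'
#' Two tiny annotations sharing one intron chain out of three, five junctions
#' out of eight, and ten boundary positions out of twelve, so that
#' [compare_annotations()] returns exactly 5/6, 5/8 and 1/3 at the boundary,
#' junction and intron-chain levels. The shared chain appears in both
#' annotations with different terminal-exon extents, illustrating that chain
#' identity ignores transcript ends.
#'
#' @return A list with two [annotation_set()] elements, `t1` and `t2`.
#' @examples
#' compare_annotations(toy_annotation_pair()$t1, toy_annotation_pair()$t2)
#' @export
toy_annotation_pair <- function() {
  # shared chain: junctions (300,400) (700,800) (900,1000)
  a1 <- transcript_model("A.1", "GA", "chr1", "+",
                         rbind(c(200, 300), c(400, 700), c(800, 900),
                               c(1000, 1080)))
  # chain unique to t1: (100,200) (300,450) (500,600) (700,900)
  a2 <- transcript_model("A.2", "GA", "chr1", "+",
                         rbind(c(50, 100), c(200, 300), c(450, 500),
                               c(600, 700), c(900, 980)))
  # shared chain again, with different first/last exon extents
  b1 <- transcript_model("B.1", "GB", "chr1", "+",
                         rbind(c(240, 300), c(400, 700), c(800, 900),
                               c(1000, 1120)))
  # chain unique to t2: (100,200) (500,600) (800,1150)
  b2 <- transcript_model("B.2", "GB", "chr1", "+",
                         rbind(c(60, 100), c(200, 500), c(600, 800),
                               c(1150, 1250)))
  list(t1 = annotation_set(list(a1, a2)),
       t2 = annotation_set(list(b1, b2)))
}

#' Toy assembly with one planted event per intron-retention criterion
#'
#' Four transcripts of one gene: `t1` is the high-abundance reference
#' (abundance 10, five exons); `t2`, `t3` and `t4` (abundance 6 each, so
#' every pairwise ratio passes the default 0.5 gate) satisfy exactly
#' criteria 1, 2 and 3 respectively — `t2`'s first exon starts inside the
#' second intron of `t1` and ends inside the following exon, `t3`'s last exon
#' extends from the fourth exon of `t1` into the fourth intron, and `t4`'s
#' second exon fully covers the second intron of `t1`. `t1` itself triggers
#' no criterion against any of them.
#'
#' @return An [annotation_set()] with transcripts `t1`..`t4`.
#' @examples
#' detect_ir(toy_ir_assembly())
#' @export
toy_ir_assembly <- function() {
  exo <- function(...) rbind(...)
  annotation_set(list(
    transcript_model("t1", "G1", "chr1", "+",
                     exo(c(100, 200), c(300, 400), c(500, 600),
                         c(700, 800), c(900, 1000)),
                     abundance = 10),
    transcript_model("t2", "G1", "chr1", "+",
                     exo(c(450, 560), c(700, 800), c(900, 1000)),
                     abundance = 6),
    transcript_model("t3", "G1", "chr1", "+",
                     exo(c(100, 200), c(300, 400), c(500, 600), c(700, 850)),
                     abundance = 6),
    transcript_model("t4", "G1", "chr1", "+",
                     exo(c(100, 200), c(350, 550), c(700, 800), c(900, 1000)),
                     abundance = 6)))
}
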