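# Reference transcript used by several geometry cases: five exons, four
# introns, on chr1:+.
.r5 <- function(ab = 10) tx("r", rbind(c(100, 200), c(300, 400), c(500, 600),
                                       c(700, 800), c(900, 1000)),
                            abundance = ab)

test_that("criterion 1: first exon must cross an acceptor into the next exon", {
  r <- .r5()
  hit <- tx("t", rbind(c(450, 560), c(700, 800)), abundance = 1)
  expect_true(check_criterion1(hit, r))
  # entirely inside the intron: never reaches the acceptor
  inside <- tx("t", rbind(c(420, 480), c(700, 800)), abundance = 1)
  expect_false(check_criterion1(inside, r))
  # identical chain: exons never overlap r's introns
  same <- tx("t", r$exons, abundance = 1)
  expect_false(check_criterion1(same, r))
  # ending exactly at the acceptor covers no exon base (half-open)
  at_edge <- tx("t", rbind(c(450, 500), c(700, 800)), abundance = 1)
  expect_false(check_criterion1(at_edge, r))
  expect_false(check_criterion1(hit, tx("single", rbind(c(100, 1000)))))
})

test_that("criterion 2: last exon must cross a donor into the intron", {
  r <- .r5()
  hit <- tx("t", rbind(c(100, 200), c(300, 400), c(500, 600), c(700, 850)),
            abundance = 1)
  expect_true(check_criterion2(hit, r))
  # ending exactly at the donor covers no intron base
  at_edge <- tx("t", rbind(c(100, 200), c(300, 400), c(500, 600), c(700, 800)),
                abundance = 1)
  expect_false(check_criterion2(at_edge, r))
  # transcript entirely left of the single intron of a two-exon reference
  r2 <- tx("r2", rbind(c(100, 200), c(500, 600)), abundance = 10)
  left <- tx("t", rbind(c(100, 180)), abundance = 1)
  expect_false(check_criterion2(left, r2))
})

test_that("criterion 3: an exon must fully cover an intron, equality included", {
  r <- .r5()
  covering <- tx("t", rbind(c(100, 200), c(350, 550), c(700, 800)),
                 abundance = 1)
  expect_true(check_criterion3(covering, r))
  exact <- tx("t", rbind(c(400, 500)), abundance = 1)       # exon == intron
  expect_true(check_criterion3(exact, r))
  one_short <- tx("t", rbind(c(400, 499)), abundance = 1)   # misses base 499
  expect_false(check_criterion3(one_short, r))
})

test_that("the min_overlap parameter tightens the spanning tests", {
  r <- .r5()
  graze <- tx("t", rbind(c(499, 510), c(700, 800)), abundance = 1)
  expect_true(check_criterion1(graze, r, min_overlap = 1L))   # 1 intron base
  expect_false(check_criterion1(graze, r, min_overlap = 5L))
})

test_that("candidate references apply chromosome, strand, span and strict ratio gates", {
  r_far <- tx("far", rbind(c(90000, 90100), c(90200, 90300)), abundance = 100)
  r_chr <- tx("chr", rbind(c(100, 200), c(300, 400)), chrom = "chr9",
              abundance = 100, gene = "G9")
  r_neg <- tx("neg", rbind(c(100, 200), c(300, 400)), strand = "-",
              abundance = 100, gene = "G2")
  r_lo <- tx("lo", rbind(c(100, 200), c(300, 400)), abundance = 5)
  r_hi <- tx("hi", rbind(c(100, 200), c(300, 400)), abundance = 5.1)
  t0 <- tx("t0", rbind(c(150, 250)), abundance = 10)
  asm <- annotation_set(list(t0, r_far, r_chr, r_neg, r_lo, r_hi))
  cand <- candidate_references(t0, asm)
  # ratio exactly at the threshold is excluded ("above" is strict)
  expect_equal(vapply(cand, `[[`, "", "transcript_id"), "hi")
  relaxed <- candidate_references(t0, asm,
                                  ir_params(require_same_strand = FALSE))
  expect_setequal(vapply(relaxed, `[[`, "", "transcript_id"), c("hi", "neg"))
  none <- candidate_references(t0, asm, ir_params(ratio_threshold = 10))
  expect_length(none, 0L)
})

test_that("the toy assembly is flagged exactly as designed", {
  asm <- toy_ir_assembly()
  calls <- detect_ir(asm)
  by_t <- split(calls$criterion, calls$t_id)
  expect_setequal(names(by_t), c("t2", "t3", "t4"))
  expect_equal(sort(unique(by_t$t2)), 1L)
  expect_equal(sort(unique(by_t$t3)), 2L)
  expect_equal(sort(unique(by_t$t4)), 3L)
  expect_false("t1" %in% calls$t_id)
  parts <- split_assembly(asm, calls)
  expect_equal(transcript_ids(parts$kept), "t1")
  expect_setequal(transcript_ids(parts$removed), c("t2", "t3", "t4"))
  # raising the gate far enough silences everything
  expect_equal(nrow(detect_ir(asm, ir_params(ratio_threshold = 10))), 0L)
})

test_that("degenerate assemblies produce no calls", {
  lone <- ann(tx("only", rbind(c(100, 200), c(300, 400)), abundance = 5))
  expect_equal(nrow(detect_ir(lone)), 0L)
  # all transcripts share one chain: exons never overlap each other's introns
  shared <- annotation_set(list(
    tx("a", rbind(c(100, 200), c(300, 400)), abundance = 1),
    tx("b", rbind(c(120, 200), c(300, 380)), abundance = 1000),
    tx("c", rbind(c(90, 200), c(300, 460)), abundance = 0.01)))
  expect_equal(nrow(detect_ir(shared)), 0L)
})

test_that("abundance handling: errors, zero-abundance skips, ignore mode", {
  no_ab <- annotation_set(list(
    tx("a", rbind(c(100, 200), c(300, 400))),
    tx("b", rbind(c(150, 350)))))
  expect_error(detect_ir(no_ab), "ignore_abundance")
  calls <- detect_ir(no_ab, ir_params(ignore_abundance = TRUE))
  expect_gt(nrow(calls), 0L)
  expect_true(all(is.na(calls$ratio)))

  zero <- annotation_set(list(
    tx("z", rbind(c(350, 550)), abundance = 0),
    tx("r", rbind(c(100, 300), c(400, 500), c(600, 800)), abundance = 5)))
  expect_warning(zcalls <- detect_ir(zero), "zero abundance")
  expect_false("z" %in% zcalls$t_id)
})

test_that("raising the threshold only ever shrinks the flagged set", {
  for (s in 1:25) {
    a <- plant_ir(small_annotation(s))$annotation
    prev <- NULL
    for (thr in c(0, 0.25, 0.5, 1, 2)) {
      flagged <- unique(detect_ir(a, ir_params(ratio_threshold = thr))$t_id)
      if (!is.null(prev)) expect_true(all(flagged %in% prev))
      prev <- flagged
    }
  }
})

test_that("detection is invariant to rescaling all abundances", {
  for (s in 1:10) {
    a <- plant_ir(small_annotation(s))$annotation
    scaled <- annotation_set(lapply(a$transcripts, function(t) {
      t$abundance <- t$abundance * 7.3
      t
    }))
    expect_equal(as.data.frame(detect_ir(scaled)), as.data.frame(detect_ir(a)))
  }
})

test_that("split_assembly partitions the assembly and validates its calls", {
  a <- plant_ir(small_annotation(4))$annotation
  calls <- detect_ir(a)
  parts <- split_assembly(a, calls)
  expect_length(intersect(transcript_ids(parts$kept),
                          transcript_ids(parts$removed)), 0L)
  expect_setequal(c(transcript_ids(parts$kept), transcript_ids(parts$removed)),
                  transcript_ids(a))
  expect_setequal(transcript_ids(parts$removed), unique(calls$t_id))
  bogus <- data.frame(t_id = "nope", r_id = "nor", criterion = 1L, ratio = 1)
  expect_error(split_assembly(a, bogus), "absent from the assembly")
  none <- split_assembly(a, detect_ir(a, ir_params(ratio_threshold = 1e9)))
  expect_equal(n_transcripts(none$kept), n_transcripts(a))
})
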