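test_that("multi-exon matching is by exact intron chain, ends ignored", {
  ref <- ann(tx("R1", rbind(c(100, 200), c(300, 400), c(500, 600))))
  longer_ends <- tx("q", rbind(c(50, 200), c(300, 400), c(500, 900)),
                    gene = "GQ")
  expect_equal(match_transcript(longer_ends, ref), "R1")
  missing_junction <- tx("q", rbind(c(100, 200), c(500, 600)), gene = "GQ")
  expect_true(is.na(match_transcript(missing_junction, ref)))
  wrong_strand <- tx("q", rbind(c(100, 200), c(300, 400), c(500, 600)),
                     strand = "-", gene = "GQ")
  expect_true(is.na(match_transcript(wrong_strand, ref)))
  expect_equal(match_transcript(wrong_strand, ref, ignore_strand = TRUE), "R1")
})

test_that("single-exon matching needs reciprocal overlap of both lengths", {
  q <- tx("q", rbind(c(0, 100)))
  ref_good <- ann(tx("R1", rbind(c(10, 100))))   # 90 = 90% of q, 100% of ref
  expect_equal(match_transcript(q, ref_good), "R1")
  ref_bad <- ann(tx("R2", rbind(c(50, 200))))    # 50 = 50% of q
  expect_true(is.na(match_transcript(q, ref_bad)))
  # asymmetric containment fails the reciprocal rule
  ref_tiny <- ann(tx("R3", rbind(c(40, 60))))    # 100% of ref, 20% of q
  expect_true(is.na(match_transcript(q, ref_tiny)))
  ref_half <- ann(tx("R4", rbind(c(50, 150))))   # 50 = 50% of each
  expect_true(is.na(match_transcript(q, ref_half)))
  expect_equal(match_transcript(q, ref_half, single_exon_min_overlap = 0.5),
               "R4")
})

test_that("evaluation identities: self-match, no-match, direct ratio", {
  a <- small_annotation(3)
  self <- evaluate_assembly(a, a)
  expect_equal(self$precision, 1)
  expect_equal(self$num_matching, self$num_assembled)

  res <- evaluate_assembly(a, annotation_set(list(
    tx("far", rbind(c(1e7, 1e7 + 100), c(1e7 + 200, 1e7 + 300))))))
  expect_equal(res$precision, 0)

  ref <- ann(tx("R1", rbind(c(100, 200), c(300, 400))))
  asm <- annotation_set(list(
    tx("a1", rbind(c(100, 200), c(300, 400)), gene = "ga"),
    tx("a2", rbind(c(90, 200), c(300, 410)), gene = "gb"),
    tx("a3", rbind(c(100, 250), c(300, 400)), gene = "gc"),
    tx("a4", rbind(c(5000, 5100), c(5200, 5300)), gene = "gd")))
  res <- evaluate_assembly(asm, ref)
  expect_equal(res$num_matching, 2L)   # a1, a2 share the chain; a3 does not
  expect_equal(res$precision, 0.5)
  expect_equal(res$precision * res$num_assembled, res$num_matching)
  dedup <- evaluate_assembly(asm, ref, dedup_chains = TRUE)
  expect_equal(dedup$num_assembled, 3L)  # a1/a2 collapse

  empty <- evaluate_assembly(annotation_set(), ref)
  expect_true(is.na(empty$precision))
  expect_equal(empty$num_assembled, 0L)
})

test_that("matching is monotone in the reference", {
  a <- small_annotation(6)
  ref_small <- annotation_set(a$transcripts[1])
  ref_big <- a
  m_small <- evaluate_assembly(a, ref_small)$matches
  m_big <- evaluate_assembly(a, ref_big)$matches
  expect_true(all(which(!is.na(m_small)) %in% which(!is.na(m_big))))
  expect_equal(evaluate_assembly(a, ref_big)$precision, 1)
})

test_that("adjusted precision removes lowest-abundance transcripts until the target", {
  ref <- ann(tx("R1", rbind(c(100, 200), c(300, 400))),
             tx("R2", rbind(c(1000, 1100), c(1200, 1300)), gene = "G2"))
  asm <- annotation_set(list(
    tx("m1", rbind(c(100, 200), c(300, 400)), gene = "ga", abundance = 1),
    tx("u1", rbind(c(5000, 5100), c(5200, 5300)), gene = "gb", abundance = 2),
    tx("m2", rbind(c(1000, 1100), c(1200, 1300)), gene = "gc", abundance = 3)))
  adj <- adjusted_precision(asm, ref, target_matching = 1L)
  expect_equal(adj$removed_ids, "m1")
  expect_equal(adj$num_matching, 1L)
  expect_equal(adj$adjusted_precision, 1 / 2)
  # target equal to current matching: nothing removed, original precision
  same <- adjusted_precision(asm, ref, target_matching = 2L)
  expect_length(same$removed_ids, 0L)
  expect_equal(same$adjusted_precision, 2 / 3)
  # all-matching assembly: adjusted precision 1.0 at any reachable target
  all_m <- annotation_set(list(
    tx("m1", rbind(c(100, 200), c(300, 400)), gene = "ga", abundance = 1),
    tx("m2", rbind(c(1000, 1100), c(1200, 1300)), gene = "gc", abundance = 3)))
  expect_equal(adjusted_precision(all_m, ref, 1L)$adjusted_precision, 1)
  expect_error(adjusted_precision(asm, ref, 5L), "exceeds")
  no_ab <- annotation_set(list(tx("m1", rbind(c(100, 200), c(300, 400)))))
  expect_error(adjusted_precision(no_ab, ref, 0L), "abundance")
})

test_that("adjusted precision always terminates exactly at the target", {
  for (s in 1:10) {
    a <- small_annotation(s)
    full <- evaluate_assembly(a, a)
    if (full$num_matching < 2L) next
    tgt <- full$num_matching %/% 2L
    adj <- adjusted_precision(a, a, tgt)
    expect_equal(adj$num_matching, tgt)
    expect_equal(adj$num_remaining,
                 full$num_assembled - length(adj$removed_ids))
  }
})

test_that("biotype crosstab counts unique chains per biotype", {
  ref <- annotation_set(list(
    tx("x1", rbind(c(100, 200), c(300, 400)), biotype = "X", gene = "g1"),
    tx("x2", rbind(c(1000, 1100), c(1200, 1300)), biotype = "X", gene = "g2"),
    tx("y1", rbind(c(5000, 5100), c(5200, 5300)), biotype = "retained_intron",
       gene = "g3"),
    tx("u1", rbind(c(9000, 9100), c(9200, 9300)), gene = "g4")))
  # other contains one of the two X chains and nothing else
  other <- ann(tx("o1", rbind(c(100, 200), c(300, 400))))
  tab <- biotype_crosstab(ref, other)
  xrow <- tab[tab$biotype == "X", ]
  expect_equal(c(xrow$n_ref, xrow$n_matched), c(2L, 1L))
  expect_equal(xrow$percent, 50)
  expect_equal(tab$n_matched[tab$biotype == "retained_intron"], 0L)
  expect_true("unlabeled" %in% tab$biotype)
  # other == ref: every biotype at 100%
  full <- biotype_crosstab(ref, ref)
  expect_equal(full$percent, rep(100, nrow(full)))
  expect_true(all(tab$n_matched <= tab$n_ref))
})

test_that("match stratification and exclusive matches follow the reference biotypes", {
  ref_a <- annotation_set(list(
    tx("a1", rbind(c(100, 200), c(300, 400)), biotype = "retained_intron",
       gene = "g1"),
    tx("a2", rbind(c(1000, 1100), c(1200, 1300)), biotype = "protein_coding",
       gene = "g2")))
  ref_b <- ann(tx("b1", rbind(c(1000, 1100), c(1200, 1300))))
  asm <- annotation_set(list(
    tx("q1", rbind(c(100, 200), c(300, 400)), gene = "qa"),
    tx("q2", rbind(c(1000, 1100), c(1200, 1300)), gene = "qb")))
  strat <- stratify_matches_by_biotype(asm, ref_a)
  expect_equal(strat$n_matching[strat$biotype == "retained_intron"], 1L)
  expect_equal(strat$n_matching[strat$biotype == "protein_coding"], 1L)
  excl <- exclusive_matches(asm, ref_a, ref_b)
  expect_equal(excl$biotype, "retained_intron")  # q2 matches both refs
  expect_equal(excl$n_exclusive, 1L)
  none <- exclusive_matches(asm, ref_a, ref_a)
  expect_equal(nrow(none), 0L)
  no_match <- stratify_matches_by_biotype(annotation_set(), ref_a)
  expect_equal(nrow(no_match), 0L)
})
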