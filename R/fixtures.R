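# Deterministic synthetic-data generation and naive reference
# implementations, so every operation in the package is testable without
# downloading an annotation. The generator emulates the aspects of real
# annotations/assemblies the methods care about — multi-exon genes whose
# transcripts share junctions, alternative transcript ends, occasional
# retained-intron-like isoforms, log-uniform abundances and Ensembl-style
# biotype labels — not read-level realism.

#' Synthetic-annotation generator parameters
#'
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param n_genes Number of genes to generate.
#' @param max_transcripts Maximum transcripts per gene (uniform 1..max).
#' @param max_exons Maximum exons of a gene's backbone transcript.
#' @param exon_len,intron_len Integer ranges (min, max) for exon and intron
#'   lengths in bases. The intron minimum must be at least 2 so planted
#'   partial-retention exons can stop strictly inside an intron.
#' @param gene_gap Bases between consecutive genes on a chromosome; keeps
#'   genes non-overlapping.
#' @param p_single_exon Probability a gene's backbone is single-exon.
#' @param p_skip_exon Probability an alternative transcript drops one
#'   internal exon (exon skipping).
#' @param p_alt_end Probability of jittering the first-exon start or
#'   last-exon end (alternative TSS/TES).
#' @param p_ir_like Probability an alternative transcript gets a
#'   retained-intron-like structure (a merged exon pair, or a terminal exon
#'   reaching into an intron), so that random assemblies exercise the
#'   detection geometry.
#' @param abundance_range Abundances are drawn log-uniformly over this range
#'   (strictly positive).
#' @param ir_plant_rate Fraction of eligible transcripts that
#'   [plant_ir()] targets.
#' @param biotypes Biotype labels sampled per transcript.
#' @param chroms Chromosome names genes are distributed over.
#' @return A list of class `"fixture_params"`.
#' @export
fixture_params <- function(seed = 1L, n_genes = 6L, max_transcripts = 5L,
                           max_exons = 8L,
                           exon_len = c(80L, 300L),
                           intron_len = c(60L, 400L),
                           gene_gap = 5000L,
                           p_single_exon = 0.1,
                           p_skip_exon = 0.35,
                           p_alt_end = 0.35,
                           p_ir_like = 0.2,
                           abundance_range = c(1, 1000),
                           ir_plant_rate = 0.25,
                           biotypes = c("protein_coding", "lncRNA",
                                        "retained_intron",
                                        "processed_transcript",
                                        "nonsense_mediated_decay"),
                           chroms = c("chr1", "chr2")) {
  stopifnot(exon_len[1L] >= 1L, intron_len[1L] >= 2L,
            abundance_range[1L] > 0,
            ir_plant_rate >= 0, ir_plant_rate <= 1,
            n_genes >= 0L, max_transcripts >= 1L, max_exons >= 1L)
  structure(as.list(environment()), class = "fixture_params")
}

# Derive an alternative transcript from a gene backbone. All perturbations
# preserve the exon invariants by construction.
.perturb_tx <- function(ex, params) {
  n <- nrow(ex)
  if (n >= 3L && stats::runif(1L) < params$p_skip_exon) {
    ex <- ex[-sample(2:(n - 1L), 1L), , drop = FALSE]
    n <- nrow(ex)
  }
  if (n >= 2L && stats::runif(1L) < params$p_ir_like) {
    kind <- sample(3L, 1L)
    i <- sample.int(n - 1L, 1L)
    a <- ex[i, 2L]
    b <- ex[i + 1L, 1L]
    half <- max(1L, (b - a) %/% 2L)
    if (kind == 1L) {                       # merge adjacent exons
      ex[i, 2L] <- ex[i + 1L, 2L]
      ex <- ex[-(i + 1L), , drop = FALSE]
    } else if (kind == 2L) {                # suffix starting inside intron i
      ex <- ex[(i + 1L):n, , drop = FALSE]
      ex[1L, 1L] <- a + half
    } else {                                # prefix ending inside intron i
      ex <- ex[1:i, , drop = FALSE]
      ex[i, 2L] <- a + half
    }
    n <- nrow(ex)
  }
  if (stats::runif(1L) < params$p_alt_end) {
    jit <- sample(10:60, 1L)
    if (stats::runif(1L) < 0.5) {
      ex[1L, 1L] <- max(0L, min(ex[1L, 1L] + sample(c(-jit, jit), 1L),
                                ex[1L, 2L] - 10L))
    } else {
      ex[n, 2L] <- max(ex[n, 1L] + 10L, ex[n, 2L] + sample(c(-jit, jit), 1L))
    }
  }
  ex
}

#' Generate a random annotation or assembly
#'
#' Genes are laid out non-overlapping along the configured chromosomes. Each
#' gene gets a backbone transcript and up to `max_transcripts - 1`
#' alternatives derived from it by exon skipping, end jitter and occasional
#' retained-intron-like changes, so transcripts of one gene share junctions.
#' Every transcript carries a log-uniform abundance and a biotype, making the
#' output usable both as a reference annotation and as a mock assembly.
#'
#' @param params A [fixture_params()] object.
#' @return An [annotation_set()]; identical across calls with the same seed.
#' @export
random_annotation <- function(params = fixture_params()) {
  stopifnot(inherits(params, "fixture_params"))
  set.seed(params$seed)
  offsets <- stats::setNames(rep(1000L, length(params$chroms)), params$chroms)
  txs <- list()
  for (gi in seq_len(params$n_genes)) {
    chrom <- sample(params$chroms, 1L)
    strand <- sample(c("+", "-"), 1L)
    gid <- sprintf("G%03d", gi)
    n_ex <- if (stats::runif(1L) < params$p_single_exon || params$max_exons == 1L) 1L
            else sample(2:params$max_exons, 1L)
    elens <- sample(params$exon_len[1L]:params$exon_len[2L], n_ex, replace = TRUE)
    ilens <- if (n_ex > 1L)
      sample(params$intron_len[1L]:params$intron_len[2L], n_ex - 1L, replace = TRUE)
    else integer()
    pos <- offsets[[chrom]]
    starts <- ends <- integer(n_ex)
    for (e in seq_len(n_ex)) {
      starts[e] <- pos
      ends[e] <- pos + elens[e]
      pos <- ends[e] + if (e < n_ex) ilens[e] else 0L
    }
    backbone <- cbind(start = starts, end = ends)
    n_tx <- sample.int(params$max_transcripts, 1L)
    for (ti in seq_len(n_tx)) {
      ex <- if (ti == 1L || n_ex < 2L) backbone else .perturb_tx(backbone, params)
      tid <- sprintf("%s.T%d", gid, ti)
      txs[[tid]] <- transcript_model(
        tid, gid, chrom, strand, ex,
        abundance = exp(stats::runif(1L, log(params$abundance_range[1L]),
                                     log(params$abundance_range[2L]))),
        biotype = sample(params$biotypes, 1L))
    }
    offsets[[chrom]] <- max(backbone[, "end"]) + params$gene_gap
  }
  annotation_set(txs)
}

#' Plant intron-retention events with known ground truth
#'
#' Adds transcripts engineered to satisfy one chosen criterion against a
#' chosen reference transcript of the input assembly: a first exon starting
#' inside an intron (criterion 1), a last exon extending into an intron
#' (criterion 2), or an internal exon pair merged across an intron
#' (criterion 3). Planted abundances are set so the ratio gate passes
#' (`p(r)/p(t) = 2 * ratio_threshold`) — or deliberately fails when
#' `pass_gate = FALSE`. Criterion 3 requires references with at least four
#' exons so the covering exon is internal; when no reference is eligible for
#' a drawn criterion another criterion is used, and assemblies without any
#' eligible reference yield an empty truth table with a message.
#'
#' @param annotation The [annotation_set()] to plant into; needs multi-exon
#'   transcripts with positive abundances.
#' @param params A [fixture_params()]; `seed` and `ir_plant_rate` are used.
#' @param ir An [ir_params()]; the planted abundances are derived from its
#'   `ratio_threshold`.
#' @param pass_gate Plant abundances that pass (`TRUE`) or fail (`FALSE`) the
#'   ratio gate. Failing plants require a strictly positive threshold.
#' @return A list: `annotation` (input plus planted transcripts) and `truth`
#'   (data frame `t_id`, `r_id`, `criterion`).
#' @export
plant_ir <- function(annotation, params = fixture_params(), ir = ir_params(),
                     pass_gate = TRUE) {
  stopifnot(inherits(annotation, "annotation_set"))
  set.seed(params$seed + 424243L)
  txs <- annotation$transcripts
  nex <- vapply(txs, function(t) nrow(t$exons), 0L)
  ab <- vapply(txs, `[[`, NA_real_, "abundance")
  eligible <- names(txs)[nex >= 2L & !is.na(ab) & ab > 0]
  if (!length(eligible)) {
    message("plant_ir: no eligible reference transcript; nothing planted")
    return(list(annotation = annotation,
                truth = data.frame(t_id = character(), r_id = character(),
                                   criterion = integer(),
                                   stringsAsFactors = FALSE)))
  }
  n_plant <- max(1L, round(params$ir_plant_rate * length(eligible)))
  if (!pass_gate && ir$ratio_threshold <= 0)
    stop("pass_gate = FALSE requires a strictly positive ratio_threshold")
  planted <- list()
  truth <- vector("list", n_plant)
  for (k in seq_len(n_plant)) {
    rid <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
    r <- txs[[rid]]
    ex <- r$exons
    n <- nrow(ex)
    allowed <- if (n >= 4L) 1:3 else 1:2
    crit <- if (length(allowed) == 1L) allowed else sample(allowed, 1L)
    if (crit == 3L) {
      i <- if (n == 4L) 2L else sample(2:(n - 2L), 1L)
      newex <- ex
      newex[i, 2L] <- ex[i + 1L, 2L]
      newex <- newex[-(i + 1L), , drop = FALSE]
    } else {
      i <- sample.int(n - 1L, 1L)
      a <- ex[i, 2L]
      b <- ex[i + 1L, 1L]
      half <- max(1L, (b - a) %/% 2L)
      if (crit == 1L) {
        newex <- ex[(i + 1L):n, , drop = FALSE]
        newex[1L, 1L] <- a + half
      } else {
        newex <- ex[1:i, , drop = FALSE]
        newex[i, 2L] <- a + half
      }
    }
    thr <- ir$ratio_threshold
    p_t <- if (pass_gate) {
      if (thr > 0) r$abundance / (2 * thr) else r$abundance
    } else {
      r$abundance / (thr / 2)
    }
    tid <- sprintf("IR%04d", k)
    planted[[tid]] <- transcript_model(tid, r$gene_id, r$chrom, r$strand,
                                       newex, abundance = p_t,
                                       biotype = "retained_intron")
    truth[[k]] <- data.frame(t_id = tid, r_id = rid, criterion = crit,
                             stringsAsFactors = FALSE)
  }
  list(annotation = annotation_set(c(txs, planted)),
       truth = do.call(rbind, truth))
}

#' Brute-force intron-retention oracle
#'
#' Evaluates the intron-retention definition by scanning every ordered
#' transcript pair and every exon-intron combination with direct loops — no
#' candidate indexing, no span pre-filter. Quadratic and slow by design;
#' intended purely as the independent oracle against which [detect_ir()] is
#' verified.
#'
#' @inheritParams detect_ir
#' @return An `ir_calls` data frame identical in shape and, by contract, in
#'   content to [detect_ir()].
#' @export
brute_force_ir <- function(assembly, params = ir_params()) {
  stopifnot(inherits(assembly, "annotation_set"))
  txs <- assembly$transcripts
  ids <- names(txs)
  m <- params$min_overlap_bases
  rows <- list()
  for (tid in ids) {
    t <- txs[[tid]]
    if (!params$ignore_abundance) {
      if (is.na(t$abundance))
        stop("transcript '", tid, "' has no abundance; ",
             "supply abundances or set ignore_abundance = TRUE")
      if (t$abundance <= 0) {
        warning("skipping transcript '", tid, "' with zero abundance",
                call. = FALSE)
        next
      }
    }
    tex <- t$exons
    nt <- nrow(tex)
    for (rid in ids) {
      if (rid == tid) next
      r <- txs[[rid]]
      if (r$chrom != t$chrom) next
      if (params$require_same_strand && r$strand != t$strand) next
      ratio <- NA_real_
      if (!params$ignore_abundance) {
        if (is.na(r$abundance))
          stop("transcript '", rid, "' has no abundance; ",
               "supply abundances or set ignore_abundance = TRUE")
        ratio <- r$abundance / t$abundance
        if (!(ratio > params$ratio_threshold)) next
      }
      rex <- r$exons
      nr <- nrow(rex)
      if (nr < 2L) next
      c1 <- c2 <- c3 <- FALSE
      for (i in seq_len(nr - 1L)) {
        a <- rex[i, 2L]
        b <- rex[i + 1L, 1L]
        if (min(tex[1L, 2L], b) - max(tex[1L, 1L], a) >= m &&
            min(tex[1L, 2L], rex[i + 1L, 2L]) -
              max(tex[1L, 1L], rex[i + 1L, 1L]) >= m)
          c1 <- TRUE
        if (min(tex[nt, 2L], rex[i, 2L]) - max(tex[nt, 1L], rex[i, 1L]) >= m &&
            min(tex[nt, 2L], b) - max(tex[nt, 1L], a) >= m)
          c2 <- TRUE
        for (e in seq_len(nt))
          if (tex[e, 1L] <= a && b <= tex[e, 2L]) c3 <- TRUE
      }
      hit <- which(c(c1, c2, c3))
      if (length(hit))
        rows[[length(rows) + 1L]] <-
          data.frame(t_id = tid, r_id = rid, criterion = hit, ratio = ratio,
                     stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(.empty_calls())
  out <- do.call(rbind, rows)
  out <- out[order(out$t_id, out$r_id, out$criterion), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ir_calls", "data.frame")
  out
}
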