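---
title: "Methods: structural comparison of annotations and intron-retention adjustment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural comparison of annotations and intron-retention adjustment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(introntools)
```

## The problem

RefSeq and Ensembl/GENCODE annotate the human transcriptome with different
methodologies, and the differences matter: a transcript assembler can look
better than a competitor under one annotation and worse under the other.
A disproportionate share of that disagreement involves transcripts with
*retained introns* — transcripts in which intronic sequence of a more
abundant isoform is (partly) included in a mature product. `introntools`
provides the machinery to quantify this: structural similarity measures
between annotations, a gene-correspondence construction, a detector that
flags retained-intron transcripts in any assembly so they can be filtered or
extracted, and a transcript-level evaluation of assemblies against
annotations.

## Transcript structure and the three structural sets

A transcript $t$ is an ordered list of exons on one chromosome and strand.
Internally all coordinates are 0-based half-open; GTF's 1-based closed
convention is converted exactly once at I/O, so interval arithmetic is
unambiguous everywhere else. Every gap between consecutive exons is an
intron, written as a junction $(d, a)$ — donor and acceptor in genomic
order. Three sets summarise the structure of $t$:

* $B(t)$ — the intron-exon **boundaries**, i.e. the donors and acceptors of
  all introns. Transcript termini are *not* boundaries, so single-exon
  transcripts have $B(t) = \emptyset$ and $|B(t)| = 2\,|J(t)|$ always holds.
* $J(t)$ — the set of **junctions**.
* $C(t)$ — the **intron chain**, the full ordered tuple of junctions. The
  chain ignores the outer extents of the terminal exons, and is the unit of
  transcript identity throughout the package.

For a gene $g$, $B(g) = \bigcup_{t \in g} B(t)$ and likewise for $J$ and
$C$; for an annotation $T$ the union runs over all genes. Similarity of two
annotations at each level is the Jaccard index, e.g.
$J_B(T_1, T_2) = |B(T_1) \cap B(T_2)| \,/\, |B(T_1) \cup B(T_2)|$.

Two conventions were genuinely open and are worth stating:

* **Strand-awareness.** Element identity includes chromosome *and* strand;
  features on strand `"."` only ever equal other `"."` features. This
  prevents spurious matches between overlapping antisense loci. Every
  comparison function accepts `ignore_strand = TRUE` to relax it.
* **Both-empty Jaccard is `NA`,** not 0 or 1. The index is undefined on two
  empty sets, and either constant would fabricate a similarity where no
  multi-exon structure exists.

## Gene correspondence

Two genes from different annotations form a pair when they share at least
one intron-exon boundary; each pair carries the three per-pair Jaccard
values. One gene may pair with several genes of the other annotation; no
greedy resolution is applied, as genes within one annotation rarely share
boundaries. `pair_genes()` finds candidates through a boundary-to-gene
inverted index and is verified against an all-pairs scan
(`pair_genes_bruteforce()`).

The pairing condition is stated in words as boundary sharing but is
sometimes written in junction notation; the two readings differ (two genes
can share a boundary without sharing a junction). The package follows the
words — boundary sharing, the weaker and therefore more inclusive condition
— and exposes `pair_on = "junction"` for the alternative, which always
yields a subset of the boundary pairs. Only genes with at least one
multi-exon transcript participate; such genes keep *all* their transcripts.

## Intron-retention detection

Transcript $t$ in an assembly has a (partial) intron retention if some other
transcript $r$ of the *same* assembly satisfies the abundance gate
$p(r)/p(t) > \theta$ (strictly; $\theta = 0.5$ by default) and one of:

1. the genomically first exon of $t$ spans an intron of $r$ and the exon
   following it — it crosses the acceptor;
2. the genomically last exon of $t$ spans an exon of $r$ and the intron
   following it — it crosses the donor;
3. some exon of $t$ fully covers some intron of $r$ (equality of endpoints
   counts as covered).

The rationale for the gate: a fragment of an incompletely spliced,
comparably abundant isoform is the canonical retained-intron artifact,
whereas structure borrowed from a much rarer transcript is weak evidence.

Operational choices, each configurable through `ir_params()`:

* **"Above the threshold" is strict** (`>`), so a ratio of exactly 0.5
  under the default never qualifies. The boundary case is tested explicitly.
* **"Spans" means at least one base on each side** of the crossed boundary
  (`min_overlap_bases = 1`, the weakest reading). Stricter containment
  readings are a parameter, not a fork.
* **First/last exon is genomic, not transcriptional.** The two partial
  criteria then mirror each other under strand flip, and unstranded
  transcripts are unambiguous.
* **$t$ and $r$ must share a strand by default**
  (`require_same_strand = TRUE`): retention is a splicing event within one
  locus.
* **Single-exon $t$ is allowed** — its sole exon is both first and last, and
  an unspliced pre-mRNA fragment is precisely what the detector exists to
  find.
* **Criteria are evaluated independently and may co-fire**; every satisfied
  (t, r, criterion) combination is reported, and "flagged" is the
  existential reduction over calls. Whether partial-retention criteria
  should exclude fully covered introns is deliberately *not* assumed; full
  coverage simply also fires criterion 3.
* **Zero-abundance transcripts are skipped with a warning** rather than
  treated as trivially flagged: a zero denominator makes the gate
  meaningless, and silently passing it would flag every transcript
  overlapping any expressed neighbour. `ignore_abundance = TRUE` disables
  the gate entirely (all ratio tests pass, ratios reported as `NA`) for
  assemblies without abundance attributes.

`split_assembly()` partitions an assembly into flagged (`removed`) and
unflagged (`kept`) parts — the *extract* and *filter* workflows — and the
partition is always disjoint and exhaustive.

## Evaluation against an annotation

A multi-exon assembled transcript *matches* when its intron chain exactly
equals that of an annotated transcript; a single-exon one matches a
single-exon annotated transcript by reciprocal overlap of at least 80% of
*both* lengths. Reciprocal overlap was chosen because it is symmetric and
version-stable; the fraction is a parameter. Precision is
matching/assembled, and the matching count is the recall proxy when the
annotation stands in for the unknown truth. Duplicate chains in an assembly
each count separately — the counting unit is assembled transcripts — with
`dedup_chains = TRUE` available to collapse them.

When two assemblies split the two metrics, the higher-recall one is trimmed
for a like-for-like comparison: transcripts are removed in order of
increasing abundance (ties broken lexically by id, for determinism) until
its matching count equals the other's, and the precision at that point is
the *adjusted precision*. Because each removal decrements the matching count
by 0 or 1, the target is always hit exactly; the implementation asserts
this on every run. Matching of one transcript never depends on the others,
so the sweep is computed from a single evaluation pass.

Biotype analyses use the chain as transcript identity: `biotype_crosstab()`
counts, per biotype, the unique chains of a biotype-labelled annotation and
how many occur in another annotation; `stratify_matches_by_biotype()` and
`exclusive_matches()` classify matching assembled transcripts by the biotype
of the annotation transcript they hit. Transcripts without a biotype group
under `"unlabeled"`.

## GTF dialects

`read_gtf()`/`write_gtf()` target the GTF flavours this toolchain meets in
practice: Ensembl/RefSeq/CHM13 annotations and StringTie2/Scallop2
assemblies. A `gtf_dialect()` names the attribute keys for ids, biotype and
abundance in precedence order; the default abundance order is `TPM`,
`FPKM`, `cov` — assemblers do not document which of their attributes should
count as "the" abundance, so the precedence is an explicit, documented
choice. Attribute parsing tolerates unquoted values and missing trailing
semicolons, and duplicate keys keep the first occurrence. Transcripts whose
exon rows span chromosomes or strands are rejected with a warning and
counted; zero-gap adjacent exons are a validation error unless
`merge_adjacent = TRUE` repairs them, because assembler output should not
contain them and silent merging hides upstream bugs. Only GTF is supported:
one well-tested dialect beats two fragile ones.

## What the synthetic generator emulates — and what it does not

`random_annotation()` produces non-overlapping genes whose transcripts
derive from a gene backbone by exon skipping, terminal jitter and occasional
retained-intron-like edits, with log-uniform abundances on [1, 1000]
(spanning the three orders of magnitude typical of expressed-transcript
abundance estimates) and Ensembl-style biotype labels. Defaults are 6 genes
with up to 5 transcripts of up to 8 exons, exons of 80–300 bp and introns
of 60–400 bp — compact but realistic gene shapes that keep the brute-force
oracle affordable. `plant_ir()` injects transcripts engineered to satisfy
exactly one chosen criterion against a chosen reference, with abundance set
to twice the gate (or half, to test the negative direction), returning
ground truth for recall checks.

The generator emulates *structural* properties only. It does not model read
coverage, sequencing error, fragment-length effects, paralogy, or the
scale of a real annotation (hundreds of thousands of transcripts). Passing
tests therefore demonstrate the correctness of the set algebra, geometry
and bookkeeping — not that any biological conclusion transfers to a
particular dataset.

## Validation scales and numerical choices

The test suite validates detection against a naive all-pairs oracle on 1000
generated assemblies (up to ~30 transcripts each), similarity and pairing
identities on 100–200 annotation pairs, planted-event recovery over 200
seeds, and GTF round trips over 100+ fixtures; these sizes were fixed once,
as the package's own validation design. All coordinates are integers, so
geometric tests are exact; the only floating-point quantities are abundance
ratios and Jaccard values, which are compared with strict inequalities
against user thresholds and never accumulated. Deterministic output
orderings — calls by (t, r, criterion), GTF rows by (chrom, start, id),
match tie-breaks by (chrom, start, id) — make every run byte-reproducible.

## Known limitations

* Exon-level or base-level similarity is out of scope; only the three
  intron-based levels are defined.
* The detector classifies retention purely geometrically within one
  assembly; it does not quantify retention from read coverage (no PSI/IR
  ratio) and never consults an external annotation for the reference
  transcript.
* Gene pairing trusts `gene_id` grouping; no positional gene inference is
  attempted.
* GFF3 is not parsed.
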