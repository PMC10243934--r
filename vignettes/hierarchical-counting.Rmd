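---
title: "Hierarchical rule-based counting of small RNA-seq reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical rule-based counting of small RNA-seq reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnacount)
```

## The problem

A small RNA sequencing library is rarely one population of molecules.
The same genomic locus can produce an annotated miRNA, its 5'- or
3'-shifted isomiRs, degradation fragments of an overlapping structural
RNA, and endogenous siRNAs antisense to the transcript. Generic counting
tools resolve overlaps by discarding ambiguous reads or by feature
priority alone; neither is adequate when the classes of interest differ
by a single nucleotide at the 5' end, by read length, or only by strand.

srnacount assigns each alignment through an ordered table of **selection
rules**. A rule combines:

* a feature-attribute filter (GFF column 2 source, column 3 type, or any
  column 9 attribute key);
* a positional-overlap selector — `Partial`, `Nested`, `Exact`,
  `5' anchored` or `3' anchored` — with two signed nucleotide shifts;
* a mismatch range matched against the alignment's `NM` edit distance;
* read-attribute filters: 5' nucleotide, length set, and strand relative
  to the feature (`Sense`/`Antisense`/`Any`);
* a positive integer **hierarchy** and a classifier label.

Selection runs in three stages. Stage 1 pairs features with rules by the
attribute filters and precomputes, per (feature, rule) pair, the shifted
*match window* that the pair can respond to. Stage 2 tests each
alignment's positional overlap and mismatch count against the candidates
retrieved from an interval index over those windows. Stage 3 tests the
read's own attributes. Among all candidates that pass, only those with
the minimum hierarchy value receive counts; everything else at the locus
is excluded. The stages are conjunctive filters — evaluating them in a
different order cannot change the outcome, only the cost — and the test
suite asserts this.

## Coordinates, shifts and anchors

Internally every interval is 0-based half-open; conversion happens once,
at the GFF/SAM parse boundary (GFF is 1-based closed, SAM `POS` is
1-based). Alignments are assumed ungapped and end-to-end, as produced by
Bowtie v1-style small RNA mapping, so the aligned length equals the
stored sequence length; soft clipping and indels are out of scope. For a
minus-strand alignment the 5' nucleotide is the complement of the last
base of the stored (reference-orientation) sequence.

Overlap shifts are expressed in the **feature's** orientation: negative
values move toward the feature's 5' side (upstream), positive toward its
3' side. For a minus-strand feature this reverses genomic direction.
Anchored selectors require exact equality between the read's 5' (or 3')
end and the feature's corresponding end shifted by the first (or second)
offset; the opposite read end may extend at most the other offset's
worth of nucleotides past the feature — a negative bound means the read
must stop short. The minimum read length under an anchored rule is
governed by the `Length` selector, not by the anchor. `Exact` compares
against the unshifted feature interval and rejects nonzero shifts at
parse time, since an exact selector with offsets is almost certainly a
user error. Because two anchored rules with different 5' offsets demand
different anchor coordinates, rules with offsets −1/0/+1 are mutually
exclusive by construction — this is what makes isomiR subclassification
safe at equal hierarchy values.

Features with undefined strand (`.`) satisfy only rules whose strand
requirement is `Any`; treating them as matching both `Sense` and
`Antisense` would silently double-count, so the conservative reading is
used and logged. The ambiguity code `N` never satisfies a concrete
nucleotide selector.

## Counting and normalization

A sequence with `n` reads (from a collapsed read identifier) and `m`
genomic alignments contributes `(n/m)/k` reads to each of the `k`
features passing selection at a locus. Both `m` and `k` are optional
factors (`normalize_by_alignments`, `normalize_by_features`). Hierarchy
is resolved independently at each alignment locus, which is the only
reading compatible with defining `k` "at the locus" for multi-mapping
sequences. When one feature passes several minimum-hierarchy rules, its
share is subdivided evenly across those rules, so feature-level totals
are invariant under splitting one rule into several mutually exclusive
ones — a property the acceptance tests check. Unassigned mass is tracked
in read-equivalents (`n/m` per unassigned alignment), which makes the
conservation identity `assigned + unassigned = mapped` hold exactly and
testable at 10⁻⁹ relative tolerance.

Library-level normalization is applied after counting: reads per million
mapped reads (`value × 10⁶ / mapped_reads`, with mapped reads counted
once per sequence, not once per alignment — the conventional reading of
"per million mapped reads"), or a per-library custom factor from the
sample sheet (e.g. derived from spike-ins). The 5' nt × length
distribution tables deliberately tally raw `n` over sequences with at
least one assigned alignment, not normalized weights: the table's role
is quality control of the captured population, and fractional weights
would obscure the read-length profile. An `all_mapped_distributions`
switch widens the denominator to every mapped sequence.

## The interval index

Candidate match windows — not raw feature intervals — are indexed in a
per-reference *step vector*: the axis `[0, L)` is partitioned into
consecutive steps, each carrying the immutable set of candidates whose
window covers it, with adjacent equal sets always merged. This canonical
form makes build order irrelevant (asserted by permutation tests) and
makes "which candidates overlap this interval in ≥1 nt" a union over the
steps the query touches. Strand is deliberately **not** an index
dimension: strand compatibility is a rule predicate in Stage 3, so a
sense-only rule failing an antisense read is an explicit rule decision,
not a silent index miss. Windows are clamped to `[0, L)` at build time
(a −1000 promoter shift near a contig edge clamps to 0, with a note in
the run log); queries slightly overhanging contig ends clamp with a
warning.

## Input formats

SAM files are read through Rsamtools (header required; BAM/CRAM and
paired-end data are out of scope). Per-sequence read counts are parsed
from collapsed read identifiers: `<prefix>_count=<int>` or
`seq<idx>_x<int>` (tiny-collapse convention), or `<id>-<int>` (FASTX
convention). Auto-detection probes the first 100 distinct identifiers
and requires a consistent match, falling back to counts of 1 with a
warning; an explicitly requested format that fails to parse is a hard
error naming the offending identifier. Alignment multiplicity `m` comes
from the `NH` tag when present, otherwise from a grouping pre-pass over
read identifiers, which keeps the tool aligner-agnostic. A missing `NM`
tag yields 0 mismatches with a one-time warning per file, matching the
common case of alignment with no mismatches allowed. Unmapped records
are tallied in library totals but never assigned.

Without a GFF, every `@SQ` reference sequence becomes one full-length
plus-strand feature and Stage 1 is bypassed — the mode used when reads
are aligned directly to miRNA hairpins or transcript sequences rather
than to a genome.

## The synthetic scenarios

`make_scenario()` generates complete input sets with known ground truth;
each emulates one counting recipe:

| scenario | what it exercises |
|---|---|
| `mirna_isomir` | 5'-anchored rules at offsets −1/0/+1 with 4 nt 3' slack, on + and − strand features |
| `rrna_vs_sirna` | hierarchy-1 sense structural-RNA rule over a permissive hierarchy-7 rule |
| `g22_g26` | antisense 5'G reads split into 22 nt and 26 nt classes at equal hierarchy |
| `promoter` | nested gene-body rule plus a −1000 nt shifted window at hierarchy 2 |
| `multimapper` | (n/m)/k sharing, including an unannotated decoy locus |
| `gffless` | direct-to-sequence counting from the SAM header |
| `random` | randomized features, rules and reads for property testing |

Read counts per sequence are drawn uniformly from small ranges (1–5 for
most scenarios), read lengths from 16–30 nt, and each scenario ships two
libraries in both collapsed and expanded (one record per read) form. The
default `random` scenario uses 200 reads, 20 features and 6 rules per
library — small enough that the full test suite, including 50 seeded
conservation scenarios and the 10⁴-case property tests, runs in a few
minutes, and large enough to hit every selector mode and the
multi-mapping paths. The generator is deterministic: one seed fixes
every file byte-for-byte.

What the generator does *not* emulate: sequencing error models and
quality strings (constant fill), adapter remnants, soft-clipped or
gapped alignments, and realistic genome composition. Passing tests
therefore demonstrate the correctness of selection, sharing and
normalization arithmetic on well-formed Bowtie-style input — not
robustness to malformed alignments or to alignment-stage artifacts.

Ground truth comes from `brute_force_assign()`, an exhaustive
per-alignment, per-feature, per-rule evaluator with no interval index
and no staging, written independently of the engine. The acceptance
tests require byte-for-byte equality (after the 6-decimal output
formatting) between the two on every scenario.

## Numerical and degenerate-input choices

* Fractional counts are written with fixed 6-decimal formatting;
  rounding for downstream differential expression is the consumer's
  concern.
* Equal-hierarchy ties never depend on row order: the resolved set is
  all minimum-hierarchy passers, and accumulation is order-independent
  (asserted by SAM record permutation tests). Alignments are also
  coordinate-sorted after parsing so floating-point accumulation order
  is fixed.
* An empty rules file, a rules row with hierarchy < 1, an unknown
  overlap keyword, or a malformed length list are parse-time errors
  citing the row number. An empty Stage-1 result is legal and logged.
* Queries on references absent from the index return no candidates;
  candidate windows that become empty after clamping are dropped with a
  note.
* A run aborts before any counting if the output directory cannot be
  created or written.

## A worked example

```{r example}
sc <- make_scenario("g22_g26", seed = 7, out_dir = tempfile())
res <- run_count(read_config(sc$paths$config))
res$counts
res$class_totals
```

The two classes capture disjoint read sets although both rules sit at
hierarchy 1: the length selectors alone make them mutually exclusive.
Outputs on disk (`feature_counts.csv`, `rule_totals.csv`,
`class_totals.csv`, `summary_stats.csv`, `nt_len_<library>.csv`, a run
log and the effective configuration) land in a timestamped directory so
a run is reproducible from its output alone.

## Known limitations

* Ungapped, single-end alignments only; no BAM/CRAM; no GTF dialect.
* Probabilistic multi-mapper rescue is out of scope — only the even
  (n/m)/k split is implemented.
* Hierarchy is resolved per alignment locus; there is no cross-locus
  arbitration for a multi-mapping sequence beyond the 1/m factor.
* The step vector is an in-memory structure rebuilt per run; it is not
  persisted.
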