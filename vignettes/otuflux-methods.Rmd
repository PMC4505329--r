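---
title: "Tracking taxonomic diversity flux across community editions with otuflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking taxonomic diversity flux across community editions with otuflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otuflux)
```

## The problem

Microbial mat communities in unstable habitats — hot-spring outflow
channels are the motivating case — are often sampled repeatedly in time
and space.  Each sampling ("edition" of the community) yields a pool of
16S rRNA V3 amplicons that is clustered into operational taxonomic units
(OTUs) at 97% identity.  Two questions then recur:

1. *Within* an edition: how rich and how even is the community
   (rarefaction, ACE, Simpson dominance, Shannon diversity)?
2. *Across* editions: which OTUs persist, which appear and disappear, and
   does the *taxonomic spread* of the OTUs — not just their number —
   expand or contract?

The second question motivates the Relative Taxonomic Diversity Index
implemented here, together with the OTU superset set-algebra it depends
on.  otuflux packages the whole chain — read filtering, alignment
distances, preclustering, OTU clustering, superset construction,
censuses, indices and association statistics — with a seeded synthetic
generator so that every stage can be validated against known ground
truth without any external sequencing data.

## The pipeline

**Read filtering.**  Raw reads are kept when their mean phred quality is
at least 20 and their length at least 100 bp
(`quality_length_filter()`).  Whether the quality criterion should be
the per-read mean or minimum is genuinely open in amplicon practice;
both are supported (`stat = "mean"` is the default, matching common
usage).  `preprocess_reads()` then screens for an intact primer plus
barcode prefix (exact match by default — an "intact" primer admits no
mismatches, though `max_mismatch` exists), trims it, discards reads
containing `N`, and can remove exact duplicates and reads that are exact
substrings of a longer read, keeping the longest (first seen on ties).
Substring detection is single-orientation: after primer screening V3
amplicons all face the same way.

**Alignment distance.**  Distances are Needleman–Wunsch global
alignments under unit costs (match 0, mismatch 1, indel 1), with
distance = (mismatch + gap columns) / alignment length.  Terminal gap
columns count by default because the amplicons cover one locus; a flag
excludes them.  Two numerical conventions make the distance exact and
reproducible across platforms: the pair is oriented canonically
(lexicographically) before the traceback, so `d(a,b) == d(b,a)` holds to
the bit, and traceback ties prefer diagonal over up over left.  The hot
loop is compiled (Rcpp); the test suite checks it against an independent
plain-R dynamic-programming oracle.

**Preclustering and OTU clustering.**  Denoising merges reads lying
within 0.02 (98% identity) of each other by single linkage — exactly the
connected components of the 0.02-threshold graph; the equivalence is
asserted against a union-find oracle over thousands of random instances.
Identical reads are collapsed first, so each precluster carries its read
count as a weight and is represented downstream by its most-abundant
(first-seen on ties) member.  OTUs are then called by agglomerative
clustering of the representatives cut at 0.03 (97% identity).  The
agglomeration rule of tree-based OTU callers varies between tools;
average linkage is the default here, configurable to single or complete.
On data whose between-OTU margins exceed
`2 * within + threshold` the choice provably cannot matter, and the
recovery tests are run on such margins.  Clusters of a single read are
removed before statistics (`remove_read_singletons()`), and each
surviving cluster gets a weighted per-column majority consensus built on
a progressive alignment to its longest member; base ties go
alphabetically, and a column whose weighted majority is a gap is
deleted.

**Richness.**  `rarefaction_curve()` is the analytic hypergeometric
expectation (no resampling noise; the tests compare it with Monte-Carlo
subsampling), and `ace_richness()` is the classical abundance-based
coverage estimator with the conventional rare/abundant split at 10
reads.  A sample whose rare class is all singletons has zero estimated
coverage; the estimate is then reported as undefined rather than a
number.

## Cross-edition set algebra and the T_r index

Merging the consensus sequences of all editions and clustering the pool
again at 0.03 yields the **OTU superset**: the full species scope of the
system.  Each superset cluster records its contributing (edition, OTU)
pairs, and its *multiplicity* — the number of **distinct** editions
represented.  For three editions the multiplicity census partitions the
superset into singletons *s*, doubletons *d* and tripletons *t*, and
when no cluster absorbed two OTUs of one edition the identity
`s + 2d + 3t = sum of edition sizes` holds exactly.  The census checks
this identity and reports any within-edition collapse explicitly; the
reference data shipped with the package satisfy the identity, which is
why collapses are treated as a diagnostic rather than silently folded
into a counting policy.  Two-sample comparisons (`pairwise_overlap()`)
are the two-edition special case: doubletons are the shared OTUs.
Higher-level comparisons (e.g. merging the two niches of one year before
comparing with another year) are composed from repeated superset
construction; no special-cased operation is needed.

With `n_i` the OTU count of phylum *i* in one edition and `N_i` the
phylum's superset count (its *taxonomic scope*), the index is

$$p_i = n_i / N_i, \qquad T_r = \sum_i p_i \sqrt{n_i},$$

summed over every phylum present in the edition, including the
unclassified bin.  `T_r` is comparative: its ceiling
`T_max = sum(sqrt(N_i))` is attained only by an edition that spans the
whole system scope.  Exact-mode `T_r` is monotone in every `n_i` and
never exceeds `T_max`; both properties are under test.

**Rounding conventions.**  The packaged reference worksheet
(`read_table2()`) was transcribed from a published table that was
evidently computed in rounded steps: `p_i` rounded to two decimals, each
product `p_i * sqrt(n_i)` rounded to two decimals, then summed.
`tr_index(..., rounding_mode = "table")` reproduces that chain, with
half-up rounding (0.125 becomes 0.13, as in the worksheet — not
banker's rounding).  Three cells of the archived table deserve note:

* Two printed `p_i` cells disagree with `round(n_i/N_i, 2)` by one unit
  in the last place (one edition's *Bacteroidetes* row, another's
  *Proteobacteria* row).  These are printing/rounding anomalies of the
  source worksheet.  Replaying the printed `p_i` column
  (`tr_table2(..., use_printed_p = TRUE)`) reproduces all three archived
  edition totals exactly; recomputing `p_i` from the counts lands a few
  hundredths below two of them.  Both paths are exposed and pinned by
  tests; neither is guessed to be "intended".
* The superset row of the unclassified bin carries the value 1 where
  every classified row carries `sqrt(N_i)` — inconsistent, but it is
  what the archived maximum (101.85) sums.  `tr_max()` computes the
  mathematically consistent `sum(sqrt(N_i))` by default and reproduces
  the archived convention with `reproduce_table2 = TRUE`.

Exact-mode recomputation from the raw counts stays within 0.5% of all
three archived totals and preserves their ordering, which is the
substantive claim the index supports.

## Abundance and environment statistics

`significance_filter()` implements the ≥ 0.01%-of-classifiable-reads
significance convention (inclusive at the cutoff; rows labelled
"Unclassified"/"Unassigned" are excluded from the denominator, with a
flag to include them).  `leaderboard()` ranks the top-*n* (default 50)
taxa by count with lexicographic tie-breaks — ties at the boundary are
resolved rather than expanding the board, keeping its length stable —
and `leaderboard_transitions()` partitions the union of several boards
by exact membership signature (common to all, each pairwise-only set,
each unique set).  Sample-pair statistics are Bray–Curtis similarity
(`2 Σ min / (Σx + Σy)`, via vegan), Euclidean distance, and Pearson
correlation with a two-sided p-value from the t transform.  Constant
input to the correlation is a domain error, not a silent zero; with very
few samples the p-values are reported but underpowered, and no
multiple-testing correction is applied (callers comparing many
taxon–variable pairs should count their tests).  Correlations are
computed on raw proportions by default; whether published values of this
kind were computed on proportions, percentages or transformed abundances
is usually unstated, and positive affine transforms do not change r.

## The synthetic generator: what it emulates, and what not

`system_design()` + `generate_system()` produce a multi-edition system
with complete ground truth: OTU references drawn by rejection sampling
to pairwise distance ≥ 0.10, per-edition copies of shared OTUs mutated
by a controlled substitution count, phylum labels per OTU, a designed
multiplicity census, skewed (lognormal) read counts, primer + barcode
prefixes, substitution errors and filter-passing quality strings.  All
randomness flows from one seed; the same seed reproduces the reads
byte-for-byte.

Key choices, made once:

* **Margins are design-enforced.**  Construction fails unless
  `min_between > 2 * within + otu_threshold`, so on generated data the
  designed census is recoverable regardless of linkage, and recovery
  failures indicate pipeline defects rather than ambiguous designs.
* **Controlled divergence, not i.i.d. mutation.**  An edition copy gets
  exactly `floor(within * L)` substitutions (1 at the defaults:
  `within = 0.01`, `L = 150`), so cross-copy distances are bounded
  deterministically instead of merely in expectation; the margin
  inequality above then has teeth.
* **At least 3 reads per OTU copy** (lognormal above that floor).  The
  floor guarantees every designed OTU survives read-singleton removal,
  and makes per-column consensus majorities decisive: with two reads, a
  single sequencing error forces a coin-flip tie that the alphabetical
  rule would settle arbitrarily, occasionally corrupting consensus
  sequences and, over many simulated systems, the census.  Read-level
  singleton handling is exercised by dedicated unit fixtures instead.
* **Substitution-only errors at 0.001/base** by default; an indel-rate
  option exists for robustness experiments.  Real single-molecule
  amplicon chemistries err more, and with characteristic homopolymer
  indels — the generator does not emulate any platform's error profile,
  chimeras, or abundance-dependent noise.  Passing recovery tests
  therefore demonstrates the correctness of the set algebra and index
  computations on margin-clean data, not robustness to real sequencer
  noise.

`generate_env_abundance()` builds an environment table from a single
latent gradient — all variables are noise-free affine images of it,
mimicking the strongly co-oscillating physicochemistry of one outflow —
and taxon abundances as `r·g + sqrt(1 − r²)·ε` with `ε ~ N(0,
noise_sd²)`, so the expected correlation with each named variable equals
its target, exactly ±1 when `noise_sd = 0`.  Because the variables are
collinear, incompatible targets for one taxon are rejected as infeasible
rather than silently averaged.

## Workflow integration and abundance bookkeeping

`run_flux_workflow()` chains the stages per edition (filter → screen and
trim → precluster → cluster → de-singleton → consensus → phylum by
majority over member-read labels) and then builds the superset, census,
overlaps, `T_r` (both modes) and diversity indices in one deterministic
report.  One deliberate deviation from the standalone preprocessing
operation: the workflow keeps duplicate reads (`drop_duplicates =
FALSE`) because read multiplicity is the abundance signal that
preclustering aggregates into weights; historical preprocessing tools
that removed duplicates carried the multiplicities along in separate
frequency files, which the integrated precluster step makes unnecessary.
The standalone `preprocess_reads()` keeps the duplicate/substring
removal contract for interoperability.

Taxonomy enters the workflow as per-read labels (ground truth from the
generator, or an external classifier's output); running a classifier is
out of scope.  With synthetic ground truth, member-majority phylum
assignment of merged clusters coincides with reclassifying their
consensus sequences.

## Problem sizes and test budgets

The validation suite uses sizes chosen to exercise every code path while
keeping a full run around a minute on one core: oracle equivalence on
1,000 random instances of up to 15 sequences (40 bp) plus 30
alignment-oracle pairs at 150 bp; end-to-end recovery of 100 randomized
designs (7–10 OTUs, three editions, ~200–300 reads each) with zero
tolerated error in census, per-phylum counts and exact-mode `T_r`;
Monte-Carlo cross-checks with 20,000–50,000 draws.  The
reference-table computations are instantaneous.

## Known limitations

* Hierarchical clustering materializes the full distance matrix;
  practical up to a few thousand unique sequences, not for raw
  million-read runs (greedy or k-mer-prescreened methods serve there).
* The consensus builder's progressive alignment to the longest member is
  adequate for tight (≤ 3%) clusters; it is not a general MSA.
* Multiplicity counts distinct editions; systems whose editions contain
  near-duplicate OTU pairs will trip the within-edition-collapse
  diagnostic, and the weighted census identity then intentionally fails.
* `T_r` is comparative across editions of one system only; its value
  depends on the hierarchic level chosen for the scopes (phylum here)
  and on the superset construction.
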