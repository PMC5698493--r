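---
title: "Inferring gene-cluster copy number and dosage from collapsed assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring gene-cluster copy number and dosage from collapsed assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgcdose)
```

## The inference problem

When a bacterial genome carries several near-identical copies of a long
region — here, a secondary-metabolite biosynthetic gene cluster — a
short-read assembler represents all copies by a single *collapsed*
contig. Three signals betray the repeat structure:

1. **Read depth.** The collapsed copy accumulates the reads of every
   copy, so its depth is an integer multiple of the single-copy
   baseline. Internal deletions private to a subset of copies appear as
   steps *within* the repeat: an interval at 5× flanked by 7× is absent
   from 2 of the 7 copies.
2. **Read pairs.** Pairs whose mates fall on different contigs (or
   straddle a breakpoint) witness adjacencies that the assembler could
   not resolve. Their strand combination distinguishes colinear
   (head-to-tail) from inverted (head-to-head, tail-to-tail) junctions
   under a forward–reverse (FR) library.
3. **Minor-allele pileups.** Substitutions private to a subset of
   copies appear as intermediate-frequency variants on the collapsed
   contig (a 1-of-7 variant at alternate fraction ≈ 1/7).

`bgcdose` implements this chain, together with the bin-quality,
degradation, codon-usage, amplicon and repeat-content analyses that
surround it in a symbiont-genome study, and a synthetic-data generator
that produces all inputs with known ground truth.

## Coverage model and its parameters

Depth is computed per base from the reference-consuming CIGAR span of
each alignment (secondary-style records can be excluded via `min_mapq`;
soft-clipped bases never count), then averaged over non-overlapping
windows.

* **`window_size` (500 bp).** Chosen so that, at the baseline depths the
  package targets (≥ 20×), the relative standard error of a window mean
  over a multi-copy repeat is a few percent — far less than the half-step
  between adjacent integer tiers — while still resolving kb-scale
  deletions. At 30× and 7 copies a 500-bp window mean has ≈ 3–4%
  relative noise against a 7.1% half-step.
* **Baseline.** The median window depth over user-designated single-copy
  regions. The median is robust to residual repeated windows inside the
  designated regions; designating whole unique contigs is usually
  sufficient.
* **Rounding.** `copy = round(depth / baseline)` with exact .5 ties
  rounded up. Segments whose depth ratio sits more than `tolerance`
  (default 0.3) from an integer are reported with a warning rather than
  silently trusted.
* **`min_segment_length` (three windows, 1.5 kb).** Contiguous runs of
  equal rounded copy become segments; shorter runs are merged into the
  neighbour with the closer mean depth. Requiring three windows rejects
  the occasional pair of adjacent windows that round to the wrong tier
  (single-window flips occur at the percent level at 20–30×; runs of
  three are vanishingly rare), at the cost that deletions shorter than
  1.5 kb are not resolved as separate segments. The simulated study
  conditions use 2-kb deletions.

Genome expansion is the deterministic sum `Σ length × copy`; with all
copies equal to 1 it returns the assembly length exactly.

**Gene dosage.** A gene's copy count is the *minimum* copy number over
the segments it overlaps. A gene inside a deleted interval is intact
exactly in the copies without the deletion, which is what the deleted
segment's (lower) tier counts; a gene crossing the deletion boundary is
truncated in every carrier, giving the same minimum. When several
deletions overlap one gene this rule equals "total copies minus copies
carrying any overlapping deletion" under the generator's nested carrier
assignment (below), and it is validated against per-copy enumeration in
the tests. The dosage summary reports intact bp against the expanded
genome size and against the expanded coding capacity
(`Σ gene length × copy` over *all* genes); the latter denominator is a
documented convention — coding-capacity figures in the literature do not
always state theirs.

## Connection graph

`mine_joins()` assigns each usable mate a candidate endpoint: a
forward-strand mate advertises the junction beyond its 3′ side (contig
tail, or the left flank of a declared breakpoint), a reverse-strand mate
the junction before its 5′ side. Pairs on different contigs, or
discordant on one contig (wrong order/orientation, or apparent insert
beyond `max_insert`), are tallied per endpoint pair and orientation.

* **`max_distance_from_end` (400 bp).** About the insert mean plus three
  standard deviations for a 300 ± 30 bp library: a spanning pair's mates
  cannot sit farther from the junction.
* **`min_support` (3).** Junction support scales with depth (tens of
  pairs per junction at 30×), so a small threshold suppresses stray
  discordant pairs without losing real edges. The threshold is
  configurable because no universal value exists.
* **Breakpoints** are taken from copy-number segment boundaries rather
  than discovered independently — the segmentation runs first and its
  deleted segments name the internal endpoints.
* **Self-loops.** A discordant pair whose mates both point off the *same*
  endpoint (e.g. both toward the cluster tail) is kept as a self-join:
  it is the signature of two repeat copies in inverted adjacency, which
  collapse onto one contig end. Colinear same-endpoint pairs are
  rejected as noise.

A contig end with no retained join edge is a *loose end*; a fully
connected linear replicon shows exactly two.

## Bin quality

Completeness is the number of distinct markers found, as a percentage of
the marker-set size (default 139). Purity is the percentage of *found*
markers that occur exactly once. The found-marker denominator is a
deliberate choice: dividing unique markers by the full set size could
never report a fully pure but incomplete bin as 100% pure, which is the
reading that matches how such tables are reported in practice.

## Degradation metrics

Pseudogene calling uses the strict rule `length ratio < 0.8` against the
best homolog — truncation by *more than* 20%; a gene at exactly 80% is
not called. Best-homolog assignment scans ranked hit tables: the first
reference-genome subject within the top `top_k` (100) ranks wins,
otherwise the overall best hit (ties broken by bitscore, then subject
length, then subject id — the table rarely needs the later keys, but the
order is fixed so results are reproducible). Length ratios are computed
in whatever unit the hit table uses (amino acids for protein tables);
the caller never mixes units. Category tables complement merged gene
spans per contig (overlapping genes are merged first), and coding
density intersects merged spans with query regions.

## Codon adaptation

RSCU follows the Sharp–Li conventions: per synonymous family of the
standard genetic code, each codon's count over the family mean, with
never-observed codons given a 0.5 pseudo-count *before* the mean is
taken, so downstream adaptiveness values stay positive. Relative
adaptiveness divides by the family maximum; CAI is the geometric mean of
w over a gene's codons excluding ATG, TGG and stops (single-codon
families carry no information; stops are not translated). Note that the
pseudo-count breaks exact scale-invariance of RSCU for families that are
only partially observed — duplicating the input changes observed counts
but not the pseudo-count; this is inherent to the convention. Category
comparisons use classical one-way ANOVA on untransformed CAI followed by
Tukey's HSD, via `stats::aov()` and `stats::TukeyHSD()`; the degenerate
all-constant input reports F = 0, p = 1 rather than 0/0.

## Amplicon classification

Reads are dereplicated by locating the forward primer (up to
`max_mismatches` substitutions) in either orientation, trimmed, and
classified by banded-free local alignment (match +1, mismatch −1, gap
−2) against the cluster reference. A read is cluster-derived iff
identity ≥ 0.97 (matches over alignment columns, gaps included) *and*
the aligned portion exceeds 0.90 of the read length — the ≥ / >
asymmetry of the two thresholds is preserved from their definitions.
The trans-AT rule flags reads whose top-500 ranked database hits include
a listed trans-AT accession. The scoring scheme is configurable; the
defaults are ordinary BLASTN-like unit scores, and raising
`min_identity` can only shrink the cluster set (tested as a
monotonicity property).

## Repeat quantification

`find_repeats()` reports maximal *exact* matches longer than 50 bp
(strict) between distinct genome positions, both strands, seeded with
51-mers and extended to maximality; self-hits, symmetric duplicates and
re-seeds on an already-covered alignment diagonal are removed. Exactness
is a deliberate simplification relative to gapped whole-genome aligners:
the >50 bp criterion is honoured exactly, approximate repeats below
exact identity are out of scope. The summary merges every participating
interval and reports the union span, locus count and genome fraction.
Equivalence with a full diagonal-scanning oracle is asserted on ≤ 2-kb
instances in the tests.

## The synthetic-data generator

`build_genome()` lays out a left unique arm, `n_copies` cluster copies
(optionally some inverted), and a right unique arm; designated deletions
are removed from carrier copies and point substitutions planted in
carrier subsets. The collapsed assembly is the three-contig
representation (unique arms + one intact cluster copy) an assembler
would produce. Choices worth knowing:

* **Background sequence** is i.i.d. at the configured GC (52%, a
  realistic bacterial value): sufficient for coverage/copy inference,
  which never looks at sequence composition beyond GC.
* **Carrier assignment is nested and deterministic**: deletion (and
  SNP) carriers are copies `2 .. 1 + n`. Copy 1 is always intact so it
  can serve as the collapsed representative, making the bookkeeping
  identity `intact = collapsed + Σ over extra copies (cluster − carried
  deletions)` exact. Consequently a deletion can be carried by at most
  `n_copies − 1` copies.
* **Reads**: fragment positions uniform over the intact chromosome;
  insert ~ Normal(300, 30) truncated at twice the read length (2 × 101
  bp); the pair count is Poisson with mean `depth × genome /
  (2 × read length)`. Alignments are emitted directly from the known
  placements — reads crossing copy junctions or deletion breakpoints
  keep their majority side and are soft-clipped on the other, as a
  local aligner would place them. Emitting alignments from truth avoids
  an aligner dependency while preserving the SAM contract (the output
  passes `samtools` validation).
* **Gene models**: full-length "homolog" proteins of 150–500 aa; a
  configurable fraction are truncated by a uniform draw from
  `truncation_range` (pseudogenes), the rest keep 85–105% of the
  homolog length, so intact genes never stray near the 0.8 boundary.
  Codon choice within synonymous families can follow a supplied
  adaptiveness table.
* **Amplicons**: reads are substrings of the reference (with
  substitution errors) or of a decoy mutated at 20% of sites — safely
  below the 90%-identity regime — with the cluster fraction binomial at
  the configured mixture.

What the generator does **not** emulate: position- and
chemistry-dependent error profiles, indels, GC-coverage bias, chimeric
fragments, multi-sample mixtures, and assembly itself (the collapsed
assembly is constructed, not assembled). Passing tests therefore
demonstrate correctness of the inference machinery under the stated
statistical model, not robustness to every artefact of real sequencing
data.

## Problem sizes and runtime

The test suite exercises the full chain on a 300-kb genome with a 20-kb
cluster at 7 copies (≈ 88,000 reads), parameter-recovery sweeps on
(copies, carriers) ∈ {(3,1), (7,2), (5,0)} at 25× over ~50–70-kb
genomes, a 10,000-read amplicon mixture, and brute-force oracle
comparisons on ≤ 10-kb (pileup) and ≤ 2-kb (repeats) instances. These
sizes keep the whole suite around two minutes on one CPU while leaving
every statistical margin (Poisson window noise vs. tier half-steps,
binomial mixture intervals) comfortably wide.

## Known limitations

* Copy numbers are assumed integral; mixed populations with fractional
  effective copy number only surface through the non-integer-ratio
  warning.
* Deletions shorter than `min_segment_length` are absorbed; lower it
  (with a smaller window or higher depth) to chase smaller events.
* Carrier counts are reported per deletion; attributing specific
  deletions to specific copies is not attempted — coverage alone cannot
  distinguish "two copies with three deletions each" from more even
  arrangements, and the package does not pretend otherwise.
* The repeat finder is exact-match only, and the amplicon aligner is a
  straightforward local DP — adequate at survey scale (10⁴ reads ×
  ≤ 1-kb references), not a BLAST replacement.
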