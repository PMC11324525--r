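---
title: "Methods: AAV integration analysis with planted ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AAV integration analysis with planted ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aavint)
```

Recombinant AAV vectors persist in transduced cells mostly as episomal
concatemers, but a fraction of genomes integrates into host chromosomes.
This package implements the two complementary assays used to characterize
that landscape — anchored-PCR short-read junction mapping (ITR-seq) and
long-read structural annotation of vector concatemers — together with a
synthetic-data generator that plants integration events with complete
ground truth. This vignette records the models, the tunable parameters,
the numerical conventions, and what the synthetic data do and do not show
about real libraries.

## The ITR-seq model

Anchored multiplex PCR amplifies from an ITR-specific primer into the
flanking host genome. The simulator and caller share one read architecture
(a documented stand-in, since primer and adapter layouts vary between
laboratories): read 1 = 20-base ITR primer anchor + residual ITR + host
flank; read 2 = 8-base sample barcode + 8-base UMI (`NNWNNWNN`, `W` one of
A/T) + host sequence from the shear point. The caller keys every accepted
read by the triple (ITR junction coordinate, adapter coordinate, UMI).

**Clone counting.** Reads at one ITR junction are PCR duplicates when they
share the adapter position *and/or* the UMI. That pairwise rule induces
chains (read A can share an adapter with B, which shares a UMI with C), so
the only order-independent closure is the connected-component count of the
sharing relation — that is what `collapse_and_count()` computes, with a
naive transitive-closure oracle cross-checking it in the tests. UMI
matching is exact string equality; adapter matching is exact by default,
with `dup_pos_tolerance` (bases of shear jitter) exposed and defaulting
to 0. The junction grouping window also defaults to 0 (exact coordinate),
since a site is defined by "the same genomic location".

**Normalization.** Genome equivalents are `input_ng * 1000 / genome_pg`
with 6.6 pg per diploid genome by default (configurable; the constant is a
convention, not a measurement). The per-sample frequency is
`n_sites * 100 / genome_equivalents`, i.e. unique integration sites per
100 genomes of input DNA.

**Mapping.** Host mapping is exact-seed (21-mers) plus full-length
mismatch verification at >= 90% identity, with reads placed at multiple
equally scoring positions reported as ambiguous and excluded from calling.
On a 400 kb random toy host, seeds are effectively unique; this mapper is
not intended for repetitive mammalian genomes (see *Limitations*).

## The long-read structure model

Each consensus read is decomposed into segments against the vector
(ITR-to-ITR) and the host:

1. k-mer anchors (k = 13, sampled every 5 bases, both strands) are
   clustered by reference, strand and (anti)diagonal; a diagonal shift of
   up to 25 bases within one cluster is interpreted as one small indel.
2. Cluster spans are refined by tolerant base-level extension (an isolated
   mismatch is crossed when ~70% of the next ten bases match, so 0.5%
   substitution errors do not fragment segments).
3. The highest-scoring set of compatible candidates is selected by
   weighted-interval scheduling on matched bases, ties broken toward fewer,
   then leftmost, segments.
4. Every internal boundary is re-derived by *exact* extension from the
   k-mer-verified anchor zone of the left segment. This is the load-bearing
   numerical convention: at a junction the last few bases often match both
   adjoining references (micro-homology), and tolerant extension can
   occasionally overrun a junction through its lookahead. Exact-match
   snapping assigns homology bases left-maximally, deterministically.

The simulator canonicalizes its truth tables with the same left-maximal
rule, so at zero error rate segment lists, junction labels, ITR records and
classifications admit exact oracle comparison. The convention is
read-direction dependent: annotating the reverse complement of a read
assigns junction homology to the other side, so per-ITR observed lengths
may differ by the homology run length (almost always <= 4 bases) between
strands, while classification, junction types, ITR counts and intact flags
are strand-invariant. No deterministic convention can be fully
strand-symmetric at tail-to-tail or head-to-head junctions, where reverse
complementation exchanges the two sides.

**Junction types** are a function of adjacent vector-segment orientations:
same orientation = head-to-tail; `+` then `-` = tail-to-tail (the copies
meet at their 3' ends); `-` then `+` = head-to-head. These labels describe
the molecule: a read and its reverse complement carry the same junctions.
(A two-copy `+`/`-` read of one interval is literally its own reverse
complement, which fixes this definition uniquely.)

**ITR integrity.** Each maximal alignment onto an ITR interval of >= 30
bases (`min_itr`) is one ITR record. An ITR is intact when its observed
length lies in the closed window [165, 173] bases; truncated ITRs record a
break-point offset, defined as the observed (retained) length, i.e. the
distance from the retained ITR terminus to the break. The generator places
break points uniformly in the B-B' palindromic-loop interval (offsets
50-85 from the ITR outer end), giving retained lengths of roughly 85-119
bases — the heterogeneous-truncation regime reported for in vivo ITRs —
with a 10% chance per ITR end of remaining intact.

**Functional cassette.** A copy carries a functional cDNA when one segment
covers the cDNA interval at >= 99% coverage and >= 98% identity with no
internal breakpoint; the promoter is "directly upstream" when the same
copy also covers the promoter interval contiguously in the same
orientation (or an adjoined same-orientation segment does, within a
10-base read gap). These thresholds are conventions exposed as parameters
(`cdna_coverage`, `cdna_identity`, `promoter_gap`); published analyses do
not print them.

**Classification.** A read is confirmed integrated (vector + flank) when a
host segment of >= 50 bases (`min_flank`) adjoins a vector segment within
`max_gap` (50 bases); `both_flanks` additionally requires host segments on
both sides of the vector run. Raising `min_flank` can only demote reads.

**Flank integrity** pools matched, mismatched, inserted and deleted bases
over host segments; percentages are of all aligned host bases
(M + X + I + D). The generator plants at most one indel per flank
(1-10 bases, interior), and indel placement is canonicalized right-shifted
on both sides, so planted operation lists are recovered exactly at zero
error rate.

## The synthetic-data generator

The generator *defines* the study conditions; its defaults are not tuned
per experiment:

* host: 4 random chromosomes of 100 kb with one 500-base N run each
  (a stand-in for a primate reference at desk scale);
* vector: seven components (5' ITR 169 bp, enhancer 300, promoter 400,
  intron 200, transgene cDNA 2400, polyA 225, 3' ITR 169), random
  sequences, toy ITRs *not* palindromic;
* 200 integration events, placed uniformly over usable non-N positions
  with >= 700 bases spacing (about one sonication fragment), clone counts
  uniform on 1..5, 0-3 PCR duplicates per clone template, distinct
  (shear position, UMI) pairs across the clones of one event — which is
  exactly the evidence structure the duplicate rule needs to separate
  clones;
* 150-base read pairs, fragment sizes N(350, 50) clamped at 160;
* 500 long reads: 50% episomal, ~3% pure host, the rest integrated at the
  planted events, 1-5 copies per concatemer, 30% orientation flips between
  successive copies (producing HT/HH/TT junctions), host flanks of
  300-1500 bases on one or both sides (50% both);
* substitution errors only, default rate 0 (consensus long reads are >99%
  accurate; an explicit error rate exercises robustness).

What the generator does **not** emulate: PCR chimeras and amplification
bias, quality-score structure, ITR secondary-structure self-similarity
(real ITRs are palindromic, which would make k-mer anchoring within an ITR
ambiguous), repetitive host sequence, multi-sample barcode demultiplexing,
and nanopore signal-level artifacts. Passing the oracle tests therefore
demonstrates the correctness of the calling logic under clean mappability,
not performance on repetitive mammalian genomes.

## Site annotation and enrichment

Gene bodies are 0-based half-open intervals; a site is genic when its
coordinate is contained in a gene body (an optional `flank_bp` extension
defaults to 0). Overlapping genes resolve to the smallest containing
interval, ties by gene id, which makes annotation independent of input
order. Expression categories follow the label-consistent reading of the
liver nx bins: not expressed (nx < 1), low [1, 10), medium [10, 100),
high (>= 100) — the four labels partition the axis. Enrichment is the
descriptive fold change (site fraction / background fraction) against
uniformly drawn random loci (chromosome proportional to non-N length);
categories with zero background fraction are reported as undefined rather
than infinite, and no significance test is attached because the fold
change itself is the reported quantity.

## Pipeline and determinism

`run_pipeline()` executes simulate → itrseq → annotation → longread from
one validated configuration, persists every intermediate under
`out_dir/<stage>/`, and assembles `report.json` / `report.tsv` purely from
the persisted stage summaries. Reports contain no timestamps, every
stochastic stage derives its RNG stream from the single seed, and stage
re-runs are skipped when a stage's outputs already match the configuration
hash (unless forced) — so identical configurations give byte-identical
reports, which the test suite asserts. The report TSV mirrors the
row names of a per-sample gene-therapy outcome table (Total / Vector /
Vector + flank (confirmed integrated) / Average no. ITRs per read /
Functional cDNA / cDNA + flank); package-specific extras are namespaced
under `aavint.*`.

## Problem sizes used in tests

The test suite exercises the full study conditions: 200-event site-calling
oracle, 500-read long-read oracle (error-free and at 0.5% substitutions),
10,000-locus enrichment backgrounds with 2,000 uniform sites, a 1,000-read
vector prep, and two complete pipeline runs for byte-identity, with
smaller fixtures for unit tests. These sizes are the package's chosen
desk-scale study conditions; the algorithms have no intrinsic size limits
beyond memory.

## Known limitations

* The exact-seed short-read mapper and k-mer segment anchoring assume
  effectively unique sequence; repetitive or palindromic references need a
  full aligner.
* Flank indel extraction supports one indel per host flank (as planted);
  complex flank rearrangements would need alignment-level ops throughout.
* Clone counting trusts UMIs literally; UMI sequencing errors would split
  clones (no UMI error-correction network is implemented, by scope).
* The adjustment linking long-read integration evidence to per-100-genome
  short-read rates is reported side by side, not modelled.
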