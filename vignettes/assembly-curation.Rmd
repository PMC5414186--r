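---
title: "Curating a long-read genome assembly: misassembly detection, anchoring, and pooled sex-region scanning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating a long-read genome assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmcurator)
```

## The problem

Long-read assemblies of vertebrate genomes — fish genomes with large,
recently expanded repeat families are a canonical example — are contiguous
enough that the main residual structural error is the *inter-chromosomal
chimera*: a contig that concatenates sequence from two different
chromosomes across a repeat the assembler could not resolve. Left in
place, a single chimeric contig corrupts the anchoring of two linkage
groups at once. This package implements the curation workflow around such
an assembly: detect chimeras from sequence evidence, adjudicate them
against two independent marker maps, break contigs at annotation-safe
positions, anchor the result into linkage-group pseudomolecules, and then
exploit the anchored assembly for a pooled-sequencing scan of
sex-determination regions. A companion module ranks candidate assemblies
(likelihood-score rank averaging and standardized PCA) and classifies
BAC-end pairs, and a report module reproduces the derived arithmetic of
the usual comparison tables.

Because the raw data behind such a project (tens of SMRT cells, several
Illumina libraries, pooled resequencing of both sexes) is far beyond a
desk-scale test, the package carries a first-class synthetic-data module:
genomes with *known* chimeric joins, marker maps, mate-pair libraries,
BAC ends and pooled allele counts, against which every stage is tested
for exact recovery.

## The dual-evidence misassembly detector

A chimeric junction leaves two independent sequence signatures:

1. **High variant density.** Long reads from the two real loci pile up
   over the junction and disagree with the consensus, so a variant caller
   reports a dense cluster of spurious variants. We count variant sites
   with quality strictly greater than 10 in non-overlapping 10 kbp
   windows and flag windows with more than 1 variant per kbp (strictly
   more than 10 per full window; the final partial window of a contig
   scales its threshold by its true width).
2. **A physical-coverage hole.** No genomic fragment of a large-insert
   (40 kbp) mate-pair library truly spans the junction, so *physical*
   (fragment/clone) coverage — the number of concordant pairs whose outer
   span covers a base, as opposed to read coverage — collapses to zero at
   the junction. Concordance requires both ends on one contig, convergent
   orientation, and an outer span within [0.5, 2] × the stated insert.
   Regions below 20× physical coverage are flagged, after masking 200 kbp
   at each contig end where spanning coverage is structurally depressed.

Flagged windows and low-coverage runs are each merged across gaps of up
to 20 kbp, and a merged variant region becomes a *dual-signal candidate*
when at least 80% of it is covered by the merged low-coverage set. These
four constants (10 kbp / >1 per kbp windowing, 20× coverage floor,
20 kbp merge distance, 0.8 overlap fraction) are the method's standard
settings and the package defaults; all are exposed as arguments.

### Adjudication against two maps

Marker maps of two independent kinds — a radiation-hybrid map and a
RAD-seq genetic map — arbitrate the candidates. A contig whose hits span
two linkage groups *conflicts* with that map; the conflict interval is
the gap between the two nearest hits of different groups, which must
contain the junction. The verdicts are:

* any map conflict → accepted (verdict `map_only` when there is no
  sequence signal, `accepted` when the dual signal coincides);
* dual signal with same-group markers flanking the region on both sides
  within 1 Mbp on some map, and no conflict → `rejected_by_maps` (the
  map vouches for contiguity; narrowing to under 1 Mbp follows the
  resolution maps provide for these events);
* dual signal with *no* marker of either map in the span → accepted on
  sequence evidence alone;
* dual signal with markers present but uninformative (e.g. flanked on
  one side only) → conservatively rejected. Acceptance therefore always
  rests on either a conflict or a marker-free dual signal.

### Breaking

`refine_break_regions()` intersects each accepted call with its
overlapping conflict intervals. The interior of a conflict interval
contains no marker of its map by construction, so the intersection
across maps is a marker-free window around the junction: breaking
anywhere inside it leaves both fragments with single-group marker
content. `choose_breakpoint()` then picks the position nearest the
region midpoint that lies outside all transcript alignments and outside
any single repeat record (breaking inside either would bisect a gene
model or a repeat copy), leftmost on distance ties, and
`break_contigs()` splits the sequence — `k` breakpoints add exactly `k`
contigs and conserve every base. On the default synthetic scenario,
re-running the whole scan on the broken assembly accepts zero candidates
(a fixed point), which the acceptance suite asserts.

## Anchoring

Contigs are assigned to the linkage group holding the plurality of their
marker hits provided that group has at least two hits (the two-marker
rule); contigs with two-marker support on several groups are *problem*
contigs — they are counted as a per-assembly misassembly metric, and
assigned to their plurality group rather than dropped, which keeps small
repetitive contigs anchorable at the cost of a recorded conflict. An
exact tie leaves the contig unanchored.

Within a group, contigs are ordered by the median map position of their
hits and oriented by the sign of the Spearman correlation between contig
position and map position — the simplest monotone criterion; maps with
co-segregating markers (tied positions) yield correlation 0 and an
explicit `ambiguous` orientation, laid out as `+`. Pseudomolecules are
built with fixed 10 kbp runs of `N` between consecutive contigs, recorded
as AGP v2.1 (so the gap count is the number of placements minus the
number of groups), and the AGP plus the contig FASTA reconstructs the
anchored FASTA byte-identically — the round-trip is tested.

## Candidate-assembly evaluation

Likelihood scores (one per sequencing library, consumed as numbers — the
likelihood model itself is out of scope) are dense-ranked within each
library, higher score = rank 1 with ties sharing a rank, and averaged
across libraries; the composite is invariant to any monotone per-library
rescaling. The metric table (likelihood scores, core-gene counts, NG50,
longest contig, total size, exon bp mapped) is also decomposed by PCA
with columns centered and scaled to unit variance so that incommensurate
scales contribute equally; constant columns are dropped with a warning,
and each component's sign is fixed so its largest-magnitude loading is
positive, making scores reproducible across platforms. BAC-end pairs are
classified with the standard five classes (unaligned / one end / correct
/ wrong orientation-or-span / split across contigs) from hits passing an
E-value < 1e-150 filter; "correct" means convergent orientation with an
outer span inside a configurable window, (50 kbp, 400 kbp) by default
for ~150 kbp clones, since no tighter bound is standard.

## The pooled sex-region scan

Two pools (one per sex) yield per-site allele counts in sync format. For
each site the two most frequent alleles (deletions counting as a fifth
allele; N excluded) define the estimator. Per-site FST is the classical
π-based form with a finite-depth correction on read counts:
π_k = n_k/(n_k−1)·2p_k q_k within each pool, π_T from the combined
counts, FST = (π_T − (π_a+π_b)/2)/π_T, defined as 0 for monomorphic
sites and NA when a pool is under the 10-read depth floor. A site is
*sex-patterned* when the homogametic pool (XX or ZZ) is fixed or nearly
fixed — minor-allele frequency at most 0.1 — while that same allele sits
at intermediate frequency, [0.3, 0.7], in the heterogametic pool: the
expected signature of a variant riding the non-recombining Y (or W)
haplotype at 50% within-pool frequency. The three thresholds are the
package's own defaults (the criterion is standard, printed threshold
values are not) and are prominent arguments of `sex_patterned()`.

Windowed tracks (10 kbp tiles of mean FST and sex-patterned count) feed
`detect_sd_region()`, which reports maximal runs of at least 5 windows
with at least 5 sex-patterned sites each, bridging single-window
dropouts; region bounds are the outermost qualifying windows. Swapping
the homogametic role converts the scan from an XY system to a ZW system
symmetrically, which the tests exercise in both directions.

## Repeat summaries and breakpoint enrichment

RepeatMasker-style annotation is summarized per (order, family): copy
count, total bp, percent of genome, mean copy length — each record counts
in full, as masker totals are conventionally reported, while
`pct_repetitive()` uses the *union* of records so nested copies never
push coverage past 100%. Enrichment around breakpoints takes the union
of ±75 kbp flanks, computes the same family stats inside it (records
clipped at region boundaries by default; an unclipped mode is provided
because either convention is defensible) and reports
100 × region% / genome% plus the mean-length difference.
`divergence_landscape()` bins record bp by divergence from the family
consensus — a proxy for insertion age — at 1% resolution.

## The synthetic scenario

`default_scenario()` fixes the study conditions used by the tests and
the acceptance script:

| parameter | value | reasoning |
|---|---|---|
| genome | 5 chromosomes × 2 Mbp | smallest scale at which 10 joins, 200 kbp end masks and 40 kbp inserts coexist |
| joins | 10 inter-chromosomal | plenty of events, still feasible from 10 Mbp |
| variant background / halo | 0.1 per kbp vs 3 per kbp within ±20 kbp | background far under the 1/kbp flag; halo far over it; halo width matches the 20 kbp merge scale |
| mate pairs | 7,500 × 40 kbp ± 4 kbp (~30× physical) | at ~30× clone coverage the sub-20× dip at a junction is ~53 kbp wide, comfortably covering the merged variant region at the 0.8 fraction; much deeper libraries shrink the dip below what the 80% rule can match |
| markers | every 50 kbp (RAD, 20% tied positions), every 150 kbp (RH) | several markers per segment side, plus ties to exercise ambiguous orientation |
| pools | 40× depth, sites every 200 bp, 1 Mbp region | a realistic pooled-resequencing depth and a region large enough for windowed detection |

Chimeras are built by cutting chromosomes into `2 × n_joins` segments and
concatenating pairs of segments from different chromosomes — each chimera
carries one junction near its middle, total sequence is conserved, and a
lift-over map records the construction so variants, mate pairs, markers
and BAC ends are all emitted in contig coordinates consistent with it.
The neutral background allele-frequency law is Beta(0.5, 0.5) truncated
to (0.05, 0.95) — an arbitrary but SFS-shaped choice, documented as such.

What the generator does *not* emulate: real repeat-driven ambiguity in
read placement (variant halos are Poisson, not alignment-derived),
sequencing error, library chimerism and duplicates, map errors, or
reference bias in the pools. Passing recovery tests therefore
demonstrates the pipeline's logic and bookkeeping, not its error rates
on real libraries.

## Numerical conventions and edge cases

* Coordinates are 0-based half-open everywhere in memory; 1-based at the
  VCF/sync/AGP/RepeatMasker file boundaries only.
* Gap bases are `N` runs of any length (engineered gaps are exact 10 kbp
  spacers, so no minimum run length is needed).
* NG50 requires an explicit genome-size estimate — there is no defensible
  default — and degrades to 0 with a warning when half the estimate is
  unreachable; ranking treats 0 as worst.
* Published-style figures are rounded half away from zero through a
  single helper (`round_half_up()`), because half-to-even would silently
  disagree with printed tables at the boundary.
* All thresholds are strict where the method's filters are strict:
  QUAL > 10, density > 1/kbp, coverage < 20×, E-value < 1e-150.
* Generators restore the caller's RNG state; identical seeds give
  byte-identical output.

## Problem sizes

Unit tests run on 4 × 500 kbp genomes; the acceptance suite and
`scripts/acceptance.R` run the full 10 Mbp / 10-join scan and the
10 Mbp / 1 Mbp-region pooled scan over five seeds each — sizes chosen so
the complete suite exercises every stage end-to-end on a laptop-class
machine in well under two minutes.
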