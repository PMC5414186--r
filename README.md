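# asmcurator

Curation toolkit for long-read genome assemblies, written for the kind of
fish-genomics project where a contiguous PacBio assembly must be screened
for inter-chromosomal chimeras, broken, anchored into linkage groups, and
then used for pooled-sequencing scans of sex-determination regions.

It is aimed at genome-project bioinformaticians who have an assembly plus
the usual companion data — variant calls from long-read alignments, a
large-insert mate-pair library, marker hits from a radiation-hybrid and a
RAD genetic map, RepeatMasker annotation, BAC-end alignments, and pooled
male/female resequencing counts — and need the curation arithmetic done
reproducibly.

## What it computes

**Misassembly scan.** A chimeric junction shows two sequence signatures
at once: a dense cluster of spurious variants in the long-read alignments
(more than 1 variant with QUAL > 10 per kbp over a 10 kbp window) and a
hole in large-insert *physical* coverage (fragment spans below 20×, with
200 kbp contig ends masked). Flagged windows and low-coverage runs are
merged across 20 kbp gaps; a merged variant region becomes a candidate
when ≥ 80% of it is covered by the low-coverage set. Candidates are
adjudicated against both maps: map conflicts (a contig whose markers span
two linkage groups) are always accepted, dual-signal regions spanned by
concordant markers are rejected, and dual-signal regions with no markers
at all are accepted on sequence evidence alone. Breaks are placed nearest
the region midpoint but outside transcripts and single repeat records.

**Anchoring.** Contigs join the linkage group holding ≥ 2 of their marker
hits (plurality on conflict, which is recorded as a *problem contig*
count), are ordered by median map position, oriented by the sign of the
rank correlation between contig and map position, and concatenated with
fixed 10 kbp `N` gaps into AGP v2.1 + FASTA, with a byte-exact round trip
between the two.

**Assembly evaluation.** Dense-rank averaging of per-library likelihood
scores, standardized PCA (`center = TRUE, scale = TRUE`, deterministic
sign convention) of the metric table, and five-class BAC-end pair
classification (E-value < 1e-150).

**Pooled sex scan.** Per-site pooled FST,
`FST = (pi_T - (pi_a + pi_b)/2) / pi_T` with `pi_k = n_k/(n_k-1) 2 p_k q_k`
on read counts, and sex-patterned variant calling — fixed or nearly fixed
(minor allele ≤ 0.1) in the homogametic pool, intermediate ([0.3, 0.7])
in the heterogametic pool — with 10 kbp windowed tracks and run-based
delimitation of sex-determination regions. Works symmetrically for XY and
ZW systems.

**Repeats and reports.** Per-family repeat summaries, ±75 kbp
breakpoint-region enrichment ratios, divergence-landscape binning, and
the old-vs-new comparison arithmetic of assembly reports (differences,
half-up percent changes, polishing-correction percentages, AGP gap
bookkeeping).

A synthetic-data module generates all of the above inputs with known
ground truth (chimeric joins, lift-over maps, engineered sex regions), so
the whole pipeline is testable end to end without any external data.

## Worked example

```r
library(asmcurator)

sc <- simulate_scenario(default_scenario(1))  # 10 Mbp, 10 chimeric joins
sc$mis$contigs
#> contig_set: 10 contigs, 1e+07 bp

calls <- scan_misassemblies(sc$mis$contigs, sc$variants, sc$pairs, sc$hits)
head(as.data.frame(accepted_calls(calls)), 3)
#>   contig  start    end hd_variants low_physcov rad_conflict rh_conflict  verdict
#> 1 ctg001 346630 554567        TRUE        TRUE         TRUE        TRUE accepted
#> 2 ctg002 335777 547272        TRUE        TRUE         TRUE        TRUE accepted
#> 3 ctg003 364987 564987        TRUE        TRUE         TRUE        TRUE accepted

call_summary(calls)$total
#> [1] 10
```

All ten engineered junctions are recovered (each accepted region contains
its truth junction), with both maps conflicting and both sequence signals
present. The report arithmetic prints publication-style figures:

```r
correction_summary(c(insertions = 1739112, substitutions = 88037,
                     deletions = 43794))
#> 1,870,943 corrections: 92.95% insertions, 4.71% substitutions, 2.34% deletions

compare_table(c(LG3 = 19325363), c(LG3 = 68550753), total = FALSE)
#>   label value_old value_new difference pct_change
#> 1   LG3  19325363  68550753   49225390      254.7
```

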