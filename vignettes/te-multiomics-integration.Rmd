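---
title: "TE-centric multi-omics integration: methods and design notes"
author: "teloopr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TE-centric multi-omics integration: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teloopr)
```

This vignette documents the statistical procedures implemented in
`teloopr`, the choices behind their parameters, what the synthetic-data
generator does and does not emulate, and the package's known
limitations. The package targets a two-genotype (wildtype versus
knockout) epigenomic design in which derepressed SINE B2 elements gain
accessibility and CTCF binding, lose methylation, and seed new
chromatin-loop anchors; each analysis stage below corresponds to one
step of that argument.

## Coordinates and interval algebra

All coordinates are 0-based half-open, converted at the file boundary
(RepeatMasker's 1-based `begin` becomes `start = begin - 1`). Chromosome
names compare as exact strings. Two consequences worth noting:

* **Abutting intervals do not overlap.** `[0,10)` and `[10,20)` share no
  base, so `region_merge()` keeps them apart and a 1-bp overlap is the
  weakest possible association everywhere in the package.
* **Fraction thresholds use `>=`.** An overlap qualifies when it covers
  at least `min_frac_query` of the query and/or at least
  `min_frac_target` of the target (`overlap_rule()`), mirroring the
  bedtools `-f 0.5 -F 0.5 -e` idiom with "overlapping at least 50%"
  semantics. The default rule is reciprocal 0.5/0.5 with
  `either_satisfies = TRUE`: a short peak fully inside a long element
  qualifies through the element side and vice versa.

Overlap detection is delegated to IRanges; the fraction rule, the
windowing convention (`make_windows()` puts the `len %% n` remainder on
the first windows, so sizes differ by at most 1 bp), and the midpoint
distance convention (`floor((start+end)/2)`) are applied on top and are
each validated against brute-force oracles in the test-suite.

## TE enrichment

Differential regions carry a direction from FDR < 0.05 and
|log2FC| >= 0.585 (a 1.5-fold change); both thresholds are arguments.
Enrichment at a hierarchy level (TE class; SINE family; B2 subtype)
always compares a foreground (the up or down set) against the full
detected-peak background — foreground must be a coordinate-subset of the
background, which is why `enrich_te()` enforces it.

Count mode counts **regions**: a region overlapping several elements of
one category counts once for that category, and once per category when
it spans categories, so per-category tables are deduplicated but
categories are not mutually exclusive. Length mode sums the **bp of the
distinct elements hit**: `observed_in` is the cumulative length of the
category's elements hit by foreground regions and `observed_out` the
length of the level's *other* hit elements (the level-complement; the
alternative complement — all level bp whether hit or not — answers a
different question, namely composition against the annotation rather
than against what the assay detected). Because adjacent bp are not
independent trials, length-mode p-values are computed (the cells are
valid counts) but fold enrichment is the primary length-mode readout;
the tests treat length-mode p only as a ranking.

Fisher's p is two-sided (enrichment direction is read off the fold
enrichment, not the tail), delegated to `stats::fisher.test`; the plain
sample odds ratio (ad/bc, with 0-cells mapping to `Inf`/0) is reported
instead of the conditional MLE because the table cells themselves are
the quantity of interest. BH adjustment runs within one level and one
direction — the family a reader scans in one panel.

Genomic annotation uses strand-aware TSS (gene start on `+`, gene end on
`-`), promoters TSS ± 3 kb (half-width configurable), and the precedence
promoter > gene body > intergenic, so a peak in a promoter that also
lies inside a gene is a promoter peak.

## DMR calling

The per-CpG statistic is the **pooled-proportion difference**: reads are
pooled across replicates within each group and
d = KO methylated/total − WT methylated/total. This deliberately
replaces kernel-smoothed t-statistics: the selection logic downstream —
empirical quantile cutoffs (q_low = 0.01, q_high = 0.99) on d, grouping
of same-sign candidate CpGs with successive gaps <= 300 bp, then the
filters n_CpG >= 3, |mean d| >= 0.1, autosomes only — is reproduced
exactly, while the smoother itself is out of scope. Equivalence to
smoothed t-statistics is not claimed; with 2 + 2 replicates the pooled
proportion is the natural sufficient statistic once smoothing is
dropped. CpGs are first coverage-filtered: at least 2 reads in at least
one sample of *each* group.

Numerical notes: quantiles are type-7 (R default), which is symmetric
under sign flips, so swapping the group labels exactly negates every
mean difference and swaps hypo/hyper calls (a tested invariant). A sign
flip inside a candidate run starts a new region, because a DMR is
directional. Fewer than 10 retained CpGs is an error — empirical
quantiles on fewer points are meaningless. The quantile cutoff is a
*competition* among CpGs: if planted/true signal makes up much more of
the genome than the tail fraction (1%), the cutoff moves into the signal
distribution and per-CpG sensitivity drops; this matters for generator
design (below) and equally for real data with very widespread
methylation loss, where a wider `q_low` is appropriate.

Quadrant integration pairs each DMR with every significant differential
peak it overlaps (>= 1 bp; the fraction rule is reserved for B2
membership, where element boundaries are meaningful). Quadrants follow
the signs (log2FC, mean difference): Q1 (+,+), Q2 (−,+), Q3 (−,−),
Q4 (+,−); zero methylation difference is grouped with "+" so the map is
total. A pair is B2 when either member overlaps a B2 element under the
rule, and a Fisher test of B2-status against Q4-membership over all
pairs quantifies whether derepressed-and-demethylated pairs concentrate
on B2.

## Motif scanning and orientation

`scan_best()` scores every window on both strands with
Σ log2(p/bg) (log2 odds), skipping windows that contain N, and reports
the single best hit — the max-score convention. Ties break to the
smaller offset, then to the `+` strand, making results deterministic.
The PWM gets a 0.01 per-cell pseudocount after column normalization, so
log-odds are finite; the background is uniform by default and
configurable to genome-estimated frequencies. The pass threshold
defaults to 80% of the maximum attainable score: a best-hit scanner
needs an explicit pass criterion for enrichment and orientation calls,
the source convention gives none, and 80%-of-max is scale-free in the
motif's information content. It is an explicit argument everywhere.

Loop orientation uses one best passing hit per anchor: convergent =
(left +, right −), divergent = (left −, right +), tandem = equal
defined strands; an anchor with no passing hit makes the loop
unclassified rather than guessing a strand. Orientation fractions are
reported over classified loops, with the unclassified count alongside.

## Loop-anchor comparison

Anchors are pooled per genotype (both ends of every loop), merged, and
matched across genotypes by >= 1 bp overlap of merged components:
unmatched KO components are new loop anchors (NLA), unmatched WT
components lost (LLA), and all matched components collapse into the
unchanged set (ULA). The element-mode Jaccard is |ULA| / (|NLA| + |LLA|
+ |ULA|). The >= 1 bp matching rule is the simplest auditable choice;
published Venn counts and Jaccard coefficients for such comparisons are
not always mutually consistent under any single convention, so the rule
is stated rather than reverse-engineered, and the permutation module
reports both z-scores and observed/expected ratios so either enrichment
convention can be read off. A loop is new iff at least one anchor
overlaps an NLA component (so new + unchanged partitions the KO loops),
lost symmetrically for WT; WT loops that are not lost are labelled
`retained` to keep the output total.

DEG linkage: a new loop anchored (>= 1 bp) on a CTCF-up-B2 region is a
B2 new loop; a DEG (p < 0.05) is linked when its promoter (TSS ± 3 kb)
overlaps either anchor of such a loop. The p threshold is deliberately
nominal (no multiplicity correction) to match the loose DEG definition
common in such designs; it is an argument.

## Permutation tests

`perm_test()` draws |query| regions from the universe uniformly
*without replacement* per iteration (the resample-from-universe scheme),
with `num_overlaps` (>= 1 bp against features) or `mean_distance`
(midpoint to nearest feature midpoint) as the statistic and 200
iterations by default. The empirical p is +1-smoothed,
(1 + #extreme)/(n_iter + 1), never exactly zero. Note that for a heavily
tied discrete statistic the smoothed empirical p is conservative by
construction; the calibration property in the test-suite therefore uses
the mean-distance statistic, whose null is effectively continuous, while
the exact hypergeometric check uses `num_overlaps`, where the null can
be enumerated.

## Signal profiles

`compute_matrix()` follows the scale-regions convention: fixed
`bin_size` flank bins (defaults 1000 bp flanks, 10 bp bins), the region
body tiled into `body_bins` equal-as-possible windows, each bin a
coverage-weighted mean of the track (absent track positions contribute
0 — bedGraph sparsity), minus-strand rows reversed so every row reads 5'
to 3'. The coverage-weighted mean is the only linear choice, giving the
tested invariants: doubling the track doubles the matrix, and profiles
of disjoint track sums add.

## The synthetic-data generator

`simulate_dataset()` produces the study conditions the package is
validated under: a 2 × 5 Mb genome of i.i.d. uniform bases; ~3,000
non-overlapping TE elements with a rodent-style class mix (55% SINE, 25%
LINE, 15% LTR, 5% DNA) and subtype mix over B3/B3A/B2_Mm2/B2_Mm1t/
B2_Mm1a; 300 genes; 3,000 ATAC peaks of which 60% sit on TE elements;
500 loops per genotype with 5 kb anchors. Planted signals, all recorded
in the truth labels:

* **Up-peak enrichment on one subtype (B3) at odds ratio 5.** Peaks
  overlapping the target subtype are assigned "up" at probability p1
  with odds(p1) = 5 × odds(p0); the baseline rate p0 = 0.08 was chosen
  so that the planted odds ratio is recoverable in *both* count and
  length mode: the length-mode fold enrichment has the closed form
  p1/(p1·s + p0(1−s)) for subtype bp-share s ≈ 0.3, which stays above 2
  only for p0 below ~0.10 — and a differential fraction under 10% is
  also the realistic regime for this kind of design. Direction labels
  are realized as exact shuffled counts, so realized rates sit within
  the ±2% audit band by construction.
* **CTCF motifs** (a 12-bp consensus PWM with 0.85-dominant columns) in
  60% of CTCF-up-B2 elements versus 10% of other B2 elements, planted
  into the sequence (reverse complement on the − strand).
* **Loops**: 70% of shared and specific loops get convergent motif
  orientation (10% divergent, 20% tandem), with strands planted at the
  two anchor centres in genomic order. KO-specific loops put one anchor
  on a motif-bearing CTCF-up-B2 element — these become the NLA and the
  B2 new loops. All anchors are mutually non-overlapping, which makes
  the anchor truth exact (NLA = the KO-specific anchors).
* **Methylation**: 50 hypomethylated regions (KO − WT = −0.3 from a 0.9
  baseline) of 10 CpGs spaced 15 bp inside TE elements (70% B2), plus 20
  hyper regions (from a 0.5 baseline) and 50,000 null CpGs, all with
  binomial reads at Poisson(10) coverage per sample, 2 + 2 samples. The
  null CpG count keeps the planted CpGs near 1% of the total, matching
  the quantile cutoff's tail mass (see the DMR competition note above);
  10 CpGs per region gives the ≥ 3-candidate grouping headroom against
  per-CpG noise at coverage 10.
* **DEG wiring**: 20 DEGs get their TSS at the partner anchor of a B2
  new loop; all other genes keep their promoters clear of new-loop
  anchors so the linked set is exactly the planted set.

What the generator does **not** emulate: real base composition or CpG
islands (the i.i.d. background is what makes the PWM null analytically
predictable), overlapping or nested TE copies and multi-part
RepeatMasker elements (each element is independent), replicate-level
biological variance in methylation (noise is purely binomial),
Hi-C contact matrices (loop lists are the input), and any read-level
artefacts. Passing the recovery tests therefore shows the *procedures*
are correct on data of known structure, not that the defaults are tuned
for any particular real dataset.

## Problem sizes and determinism

The test-suite runs its oracle comparisons on hundreds of randomized
small instances, unit tests on a reduced bundle (2 × 0.4 Mb, 300 TEs, 60
loops), and the recovery and determinism checks on the full default
bundle above; the permutation calibration uses 500 replicates of a
40-region universe at 200 iterations. These sizes keep the whole suite
in the low minutes while leaving every statistical check adequately
powered. All randomness flows from explicit seeds: the generator runs
under a local RNG state (the caller's stream is untouched), and
`run_pipeline()` derives its permutation seeds from the configuration
seed, so a rerun writes a byte-identical summary.

## Known limitations

* Length-mode Fisher p-values treat bp as trials; with megabase-scale
  cells they underflow toward 0 and can tie across categories — rank on
  fold enrichment there.
* The DMR stand-in statistic is undefined for CpGs with zero pooled
  coverage in a group (they are skipped) and its quantile cutoffs adapt
  to the dataset; calls are not comparable across datasets the way a
  fixed-threshold method's would be.
* `distance_to_nearest()` returns NA on chromosomes without anchors;
  downstream means propagate that NA deliberately.
* The anchor-matching rule (>= 1 bp on merged components) is one of
  several defensible conventions; Jaccard values are only comparable
  under the same rule.
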