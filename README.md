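# teloopr

Transposable-element-centric integration of epigenomic peaks, DNA
methylation and chromatin loops in a knockout-versus-wildtype design.

## The problem

Transposable elements (TEs) — in rodents, especially the SINE B2 family —
carry regulatory sequence, including CTCF binding sites, that is normally
kept silent by repressive chromatin (H3K9me3, DNA methylation). When that
repression is lifted (e.g. by knocking out a histone methyltransferase),
B2 elements can gain chromatin accessibility and CTCF binding, lose DNA
methylation, and seed new chromatin-loop anchors, rewiring 3D genome
architecture and gene expression. Testing that chain of events requires a
set of analyses that cut across assays:

- assigning differential peaks (ATAC-seq / ChIP-seq) to the RepeatMasker
  **class / family / subtype** hierarchy under reciprocal-fraction overlap
  rules (the bedtools `-f 0.5 -F 0.5 -e` convention), and testing
  enrichment by **element count** and by **cumulative length** with
  Fisher's exact test, Benjamini–Hochberg adjusted per level;
- calling **differentially methylated regions (DMRs)** from per-CpG
  counts: a per-CpG statistic, empirical quantile cutoffs (1%/99%),
  grouping of same-sign candidate CpGs within `maxGap = 300` bp, and the
  filters ≥ 3 CpGs, |mean difference| ≥ 0.1, autosomes only;
- **quadrant integration** of methylation difference against
  accessibility log2 fold-change (the fourth quadrant — hypomethylated
  and more accessible — is where derepressed B2 elements should sit);
- **log-odds PWM scanning** (best hit per region on both strands, the
  max-score convention) for CTCF motif enrichment and orientation;
- comparing chromatin-loop anchors between genotypes into **new / lost /
  unchanged anchors** (NLA / LLA / ULA), classifying loops, calling
  **convergent / divergent / tandem** CTCF motif orientation at anchor
  pairs, and linking differentially expressed genes (DEGs, *P* < 0.05) to
  new loops anchored on CTCF-gaining B2 elements;
- **resample-from-universe permutation tests** (draw |query| regions from
  a universe without replacement, 200 iterations, +1-smoothed empirical
  p) for region-set associations;
- **scale-regions signal profiles** (fixed flank bins, scaled body bins,
  coverage-weighted means) over region sets.

`teloopr` implements this pipeline as reusable, tested R functions, plus a
synthetic-data generator that plants every signal (peak enrichment on a
chosen B2 subtype, motif instances with controlled orientation,
hypomethylated regions, genotype-specific loop anchors, DEG-loop wiring)
with known ground truth, so the whole analysis can be exercised and
validated end to end without any external sequencing data.

## Core statistics

For a category *c* at a hierarchy level, the enrichment table is

|            | hits category | misses |
|------------|---------------|--------|
| foreground | a             | b      |
| background | c             | d      |

with fold enrichment FE = (a/(a+b)) / (c/(c+d)) and a two-sided exact
hypergeometric p, BH-adjusted across the level's categories. In count
mode the cells are region counts (deduplicated per region and category);
in length mode they are cumulative bp of the distinct elements hit, with
fold enrichment as the primary readout.

The permutation z-score is z = (obs − mean(null)) / sd(null) and the
empirical p is (1 + #{null ≥ obs}) / (n_iter + 1) for the greater tail.

Motif scores are Σ_j log2(p_j(base)/bg(base)) over PWM columns, best
window over both strands; a hit passes at ≥ 80% of the maximum attainable
score by default.

## Worked example

```r
library(teloopr)
r <- run_pipeline(synthetic_config(seed = 1), quiet = TRUE)
print(r)
#> pipeline_report
#>   ATAC: 3000 peaks (276 up, 136 down); top up B2 subtype: B3 (FE 3.27)
#>   DMRs: 69 (49 hypo); quadrant pairs 12 (B2~Q4 FE 1.31)
#>   Anchors: 300 NLA / 300 LLA / 700 ULA, Jaccard 0.538
#>   Loops: 150 new, 150 lost, 350 unchanged; convergent 0.69
```

The generator planted up-peaks on the B3 subtype at odds ratio 5, and the
enrichment stage recovers it:

```r
subset(r$te_enrichment, level == "b2_subtype" & direction == "up" & mode == "count")
#>  category observed_in background_in fold_enrichment    p_adj
#>   B2_Mm1a           5            48           1.132 8.01e-01
#>   B2_Mm1t           5            84           0.647 5.49e-01
#>    B2_Mm2           5           104           0.523 2.70e-01
#>        B3          49           163           3.268 4.52e-11
#>       B3A          17           124           1.490 2.70e-01
```

49 of the 276 up peaks sit on B3 elements versus 163 of the 3000
background peaks — a 3.3-fold enrichment; the other four subtypes stay at
background rates. The same report carries the DMR calls (49 of the 50
planted hypomethylated regions recovered at the default filters), the
loop-anchor comparison (300 new anchors, all placed by the generator on
motif-bearing B2 elements), the recovered ~0.69 convergent motif fraction
(0.70 planted), and three permutation tests, e.g. NLA versus CTCF-up-B2
peaks at z ≈ 18.5 with an observed/expected ratio of 2.9.

Individual stages are plain functions — `read_regions()`,
`region_intersect()`, `enrich_te()`, `call_dmrs()`,
`quadrant_integration()`, `scan_best()`, `classify_anchors()`,
`orient_loops()`, `perm_test()`, `compute_matrix()` — and every file
format (BED/narrowPeak, BEDPE, RepeatMasker .out, bedGraph, FASTA,
JASPAR PWM, CpG/DEG/gene TSV) has a reader and writer in `R/io.R`.

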