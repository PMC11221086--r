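Package: teloopr
Title: Transposable-Element-Centric Integration of Epigenomic Peaks,
    Methylation and Chromatin Loops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for transposable-element (TE) centric integration of
    multi-omics epigenomic data in a knockout-versus-wildtype design.
    Assigns differential peaks (ATAC-seq, ChIP-seq) to the RepeatMasker
    class/family/subtype hierarchy using reciprocal-fraction overlap rules,
    computes Fisher-based enrichment by element count and by cumulative
    length, calls and filters differentially methylated regions from
    per-CpG counts, integrates methylation difference with accessibility
    fold-change by quadrant, classifies chromatin-loop anchors into
    new/lost/unchanged sets, calls CTCF motif orientation at loop anchors
    from log-odds PWM scanning, evaluates region-set associations with
    resample-from-universe permutation tests, and aggregates signal tracks
    over region sets in the scale-regions convention. A synthetic-data
    generator plants every signal with known ground truth so the whole
    pipeline can be exercised and validated end to end without external
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
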