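# Differentially methylated regions from per-CpG counts, and quadrant
# integration of methylation difference against accessibility fold-change.

group_cols <- function(x, group) which(x$groups == group)

#' Coverage-filter a CpG table
#'
#' A CpG is retained iff it is covered by at least `min_reads` reads in at
#' least one sample of each genotype group (WT and KO).
#'
#' @param x `cpg_table` object.
#' @param min_reads minimum coverage (default 2).
#' @return filtered `cpg_table`.
#' @export
filter_cpgs <- function(x, min_reads = 2) {
  stopifnot(inherits(x, "cpg_table"))
  if (length(x$pos) == 0) return(x)
  wt <- group_cols(x, "WT"); ko <- group_cols(x, "KO")
  keep <- apply(x$total[, wt, drop = FALSE], 1, max) >= min_reads &
    apply(x$total[, ko, drop = FALSE], 1, max) >= min_reads
  cpg_table(x$chrom[keep], x$pos[keep], x$meth[keep, , drop = FALSE],
            x$total[keep, , drop = FALSE], x$groups)
}

#' Per-CpG pooled methylation difference (KO - WT)
#'
#' Reads are pooled across replicates within each group; the statistic is
#' the difference of pooled methylation proportions. This is the per-CpG
#' statistic used for DMR candidate selection (a deliberate simplification
#' of kernel-smoothed t-statistics: same selection logic, no smoother).
#'
#' @param x `cpg_table` object.
#' @return numeric vector, one value per CpG (`NA` where a group has zero
#'   pooled coverage).
#' @export
cpg_meth_diff <- function(x) {
  wt <- group_cols(x, "WT"); ko <- group_cols(x, "KO")
  wt_m <- rowSums(x$meth[, wt, drop = FALSE]); wt_t <- rowSums(x$total[, wt, drop = FALSE])
  ko_m <- rowSums(x$meth[, ko, drop = FALSE]); ko_t <- rowSums(x$total[, ko, drop = FALSE])
  ifelse(wt_t > 0 & ko_t > 0, ko_m / ko_t - wt_m / wt_t, NA_real_)
}

default_autosomes <- function(chroms) setdiff(unique(chroms), c("chrX", "chrY", "chrM"))

#' Call differentially methylated regions
#'
#' Candidate CpGs are those whose pooled methylation difference (KO - WT,
#' [cpg_meth_diff()]) falls below the `q_low` or above the `q_high`
#' empirical quantile of all retained CpGs. Same-sign candidates with
#' successive gaps `<= max_gap` bp form candidate regions; a region is a
#' DMR iff it contains at least `min_cpg` CpGs, its mean difference is at
#' least `min_abs_diff` in absolute value, and it lies on an autosome.
#'
#' @param x `cpg_table`, already coverage-filtered ([filter_cpgs()]).
#' @param q_low,q_high empirical quantile cutoffs (defaults 0.01 / 0.99).
#' @param max_gap maximum gap between successive candidate CpGs (300 bp).
#' @param min_cpg minimum CpGs per DMR (3).
#' @param min_abs_diff minimum |mean difference| (0.1).
#' @param autosomes chromosomes eligible for DMRs; default: every
#'   chromosome present except chrX, chrY, chrM.
#' @return sorted region table with `n_cpg`, `mean_diff`, `avg_meth`,
#'   `status` (`hypo` iff `mean_diff < 0`, else `hyper`). Intervals span
#'   the first to last candidate CpG (+1 bp, half-open).
#' @export
call_dmrs <- function(x, q_low = 0.01, q_high = 0.99, max_gap = 300,
                      min_cpg = 3, min_abs_diff = 0.1, autosomes = NULL) {
  stopifnot(inherits(x, "cpg_table"), q_low > 0, q_high < 1, q_low < q_high)
  d <- cpg_meth_diff(x)
  ok <- !is.na(d)
  if (sum(ok) < 10) stop("fewer than 10 retained CpGs: quantile cutoffs unstable")
  if (is.null(autosomes)) autosomes <- default_autosomes(x$chrom)
  cuts <- stats::quantile(d[ok], probs = c(q_low, q_high), names = FALSE)
  cand <- which(ok & (d < cuts[1] | d > cuts[2]))
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      strand = character(), n_cpg = integer(),
                      mean_diff = numeric(), avg_meth = numeric(),
                      status = character(), stringsAsFactors = FALSE)
  if (length(cand) == 0) return(empty)
  chrom <- x$chrom[cand]; pos <- x$pos[cand]; dc <- d[cand]
  sgn <- sign(dc)
  brk <- c(TRUE, chrom[-1] != chrom[-length(cand)] |
             pos[-1] - pos[-length(cand)] > max_gap |
             sgn[-1] != sgn[-length(cand)])
  grp <- cumsum(brk)
  all_m <- rowSums(x$meth); all_t <- rowSums(x$total)
  rows <- lapply(split(seq_along(cand), grp), function(i) {
    idx <- cand[i]
    md <- mean(dc[i])
    data.frame(chrom = chrom[i][1], start = min(pos[i]), end = max(pos[i]) + 1,
               strand = ".", n_cpg = length(i), mean_diff = md,
               avg_meth = sum(all_m[idx]) / sum(all_t[idx]),
               status = if (md < 0) "hypo" else "hyper",
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[res$n_cpg >= min_cpg & abs(res$mean_diff) >= min_abs_diff &
               res$chrom %in% autosomes, , drop = FALSE]
  if (nrow(res) == 0) return(empty)
  sort_regions(res)
}

#' Quadrant integration of DMRs with differential accessibility
#'
#' Pairs each DMR with every significant differential peak it overlaps
#' (>= 1 bp) and classifies the pair into a quadrant by the signs of the
#' peak's log2 fold-change and the DMR's methylation difference:
#' Q1 (+,+), Q2 (-,+), Q3 (-,-), Q4 (+,-) — the fourth quadrant is
#' hypomethylated and more accessible. A pair `is_b2` when either member
#' overlaps a B2 element under the rule. A Fisher test of
#' B2-status x Q4-membership over all pairs quantifies whether B2 pairs
#' concentrate in the fourth quadrant.
#'
#' @param dmrs DMR table from [call_dmrs()].
#' @param atac_diff differential region table; rows with `direction == "ns"`
#'   are dropped.
#' @param b2_elements region table of B2 elements.
#' @param rule [overlap_rule()] used for B2 membership.
#' @return list with `pairs` (one row per overlapping pair: DMR and peak
#'   coordinates, `log2fc`, `mean_diff`, `quadrant`, `is_b2`) and `fisher`
#'   (cells, `fold_enrichment` of Q4 among B2 pairs over all pairs, `p`);
#'   `fisher` is `NULL` when there are no pairs.
#' @export
quadrant_integration <- function(dmrs, atac_diff, b2_elements,
                                 rule = overlap_rule()) {
  atac <- atac_diff[atac_diff$direction != "ns", , drop = FALSE]
  atac <- sort_regions(atac); dmrs <- sort_regions(dmrs)
  b2 <- sort_regions(b2_elements)
  p <- overlap_pairs(dmrs, atac)
  if (nrow(p) == 0) {
    warning("no overlapping (DMR, peak) pairs")
    return(list(pairs = data.frame(), fisher = NULL))
  }
  dmr_b2 <- rep(FALSE, nrow(dmrs))
  atac_b2 <- rep(FALSE, nrow(atac))
  if (nrow(b2) > 0) {
    dmr_b2[unique(region_intersect(dmrs, b2, rule)$query_i)] <- TRUE
    atac_b2[unique(region_intersect(atac, b2, rule)$query_i)] <- TRUE
  }
  lfc <- atac$log2fc[p$target_i]
  md <- dmrs$mean_diff[p$query_i]
  quadrant <- ifelse(lfc > 0, ifelse(md >= 0, 1L, 4L), ifelse(md >= 0, 2L, 3L))
  pairs <- data.frame(
    chrom = dmrs$chrom[p$query_i],
    dmr_start = dmrs$start[p$query_i], dmr_end = dmrs$end[p$query_i],
    peak_start = atac$start[p$target_i], peak_end = atac$end[p$target_i],
    log2fc = lfc, mean_diff = md, quadrant = quadrant,
    is_b2 = dmr_b2[p$query_i] | atac_b2[p$target_i],
    stringsAsFactors = FALSE
  )
  a <- sum(pairs$is_b2 & pairs$quadrant == 4L)
  b <- sum(pairs$is_b2 & pairs$quadrant != 4L)
  cc <- sum(!pairs$is_b2 & pairs$quadrant == 4L)
  d <- sum(!pairs$is_b2 & pairs$quadrant != 4L)
  n <- nrow(pairs)
  fe <- if ((a + b) > 0 && (a + cc) > 0) (a / (a + b)) / ((a + cc) / n) else NA_real_
  ft <- fisher_test(a, b, cc, d)
  list(pairs = pairs,
       fisher = list(b2_q4 = a, b2_not_q4 = b, nonb2_q4 = cc, nonb2_not_q4 = d,
                     fold_enrichment = fe, odds_ratio = ft$odds_ratio, p = ft$p))
}
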