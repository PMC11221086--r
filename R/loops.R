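# Loop-anchor genotype comparison (new / lost / unchanged anchors),
# loop-level classification, CTCF motif orientation at anchor pairs,
# binned per-anchor peak profiles, and DEG-promoter linkage to loops
# anchored on CTCF-up B2 elements.

#' Classify loop anchors between genotypes
#'
#' Anchors are pooled per genotype (both ends of every loop), merged into
#' disjoint components, and matched across genotypes by >= 1 bp overlap.
#' Unmatched KO components are new loop anchors (NLA), unmatched WT
#' components lost loop anchors (LLA), and the matched components of both
#' genotypes collapse into the unchanged set (ULA). The element-mode
#' Jaccard coefficient is `|ULA| / (|NLA| + |LLA| + |ULA|)`.
#'
#' @param wt_loops,ko_loops loop tables ([loops()]); non-empty.
#' @return object of class `anchor_classification`: region tables `nla`,
#'   `lla`, `ula` and the scalar `jaccard`.
#' @export
classify_anchors <- function(wt_loops, ko_loops) {
  if (nrow(wt_loops) == 0 || nrow(ko_loops) == 0) {
    stop("need at least one loop per genotype")
  }
  wt_m <- region_merge(loop_anchors(wt_loops)[, c("chrom", "start", "end")] |> sort_regions())
  ko_m <- region_merge(loop_anchors(ko_loops)[, c("chrom", "start", "end")] |> sort_regions())
  p <- overlap_pairs(ko_m, wt_m)
  ko_matched <- seq_len(nrow(ko_m)) %in% p$query_i
  wt_matched <- seq_len(nrow(wt_m)) %in% p$target_i
  nla <- ko_m[!ko_matched, , drop = FALSE]
  lla <- wt_m[!wt_matched, , drop = FALSE]
  matched <- rbind(ko_m[ko_matched, c("chrom", "start", "end")],
                   wt_m[wt_matched, c("chrom", "start", "end")])
  ula <- if (nrow(matched) > 0) region_merge(sort_regions(matched)) else {
    out <- regions(character(), numeric(), numeric()); out$n_merged <- integer(); out
  }
  total <- nrow(nla) + nrow(lla) + nrow(ula)
  structure(list(nla = sort_regions(nla), lla = sort_regions(lla),
                 ula = sort_regions(ula),
                 jaccard = if (total > 0) nrow(ula) / total else NaN),
            class = "anchor_classification")
}

#' @export
print.anchor_classification <- function(x, ...) {
  cat(sprintf("anchor classification: %d NLA, %d LLA, %d ULA (Jaccard %.3f)\n",
              nrow(x$nla), nrow(x$lla), nrow(x$ula), x$jaccard))
  invisible(x)
}

# which loops of `lp` have >= 1 anchor overlapping >= 1 bp of `set`
loops_touching <- function(lp, set) {
  if (nrow(lp) == 0 || nrow(set) == 0) return(rep(FALSE, nrow(lp)))
  anch <- loop_anchors(lp)
  p <- overlap_pairs(anch, sort_regions(set[, c("chrom", "start", "end")]))
  seq_len(nrow(lp)) %in% unique(anch$loop_id[unique(p$query_i)])
}

#' Classify loops as new / lost / unchanged / retained
#'
#' A KO loop is `new` iff at least one of its anchors overlaps an NLA
#' component, else `unchanged`; a WT loop is `lost` iff at least one anchor
#' overlaps an LLA component, else `retained`. Every KO loop receives
#' exactly one of new/unchanged.
#'
#' @param wt_loops,ko_loops loop tables.
#' @param cls [classify_anchors()] result computed from the same lists.
#' @return loop table (KO rows first) with a `klass` column.
#' @export
classify_loops <- function(wt_loops, ko_loops, cls) {
  stopifnot(inherits(cls, "anchor_classification"))
  ko <- ko_loops
  ko$klass <- ifelse(loops_touching(ko, cls$nla), "new", "unchanged")
  wt <- wt_loops
  wt$klass <- ifelse(loops_touching(wt, cls$lla), "lost", "retained")
  rbind(ko, wt)
}

#' CTCF motif orientation at loop anchor pairs
#'
#' Uses one best hit per anchor (from [scan_regions()]): the anchor strand
#' is the hit strand when the hit passes the threshold, else `none`.
#' Orientation: convergent iff (left `+`, right `-`), divergent iff
#' (left `-`, right `+`), tandem iff both strands equal and defined,
#' unclassified iff either anchor has no passing hit.
#'
#' @param lp loop table.
#' @param left_hits,right_hits data.frames from [scan_regions()] over the
#'   left / right anchors of `lp` (same row order).
#' @return list with `calls` (loop table + `left_strand`, `right_strand`,
#'   `orientation`) and `summary` (fractions of classified loops per
#'   orientation plus the unclassified count).
#' @export
orient_loops <- function(lp, left_hits, right_hits) {
  stopifnot(nrow(left_hits) == nrow(lp), nrow(right_hits) == nrow(lp))
  ls <- ifelse(left_hits$passes, left_hits$strand, "none")
  rs <- ifelse(right_hits$passes, right_hits$strand, "none")
  orientation <- ifelse(ls == "none" | rs == "none", "unclassified",
                 ifelse(ls == "+" & rs == "-", "convergent",
                 ifelse(ls == "-" & rs == "+", "divergent", "tandem")))
  calls <- lp
  calls$left_strand <- ls; calls$right_strand <- rs
  calls$orientation <- orientation
  n_cls <- sum(orientation != "unclassified")
  summary <- list(
    convergent = if (n_cls > 0) sum(orientation == "convergent") / n_cls else NaN,
    divergent = if (n_cls > 0) sum(orientation == "divergent") / n_cls else NaN,
    tandem = if (n_cls > 0) sum(orientation == "tandem") / n_cls else NaN,
    n_classified = n_cls,
    n_unclassified = sum(orientation == "unclassified")
  )
  list(calls = calls, summary = summary)
}

#' Binned peak profile over anchors
#'
#' Each anchor is tiled into `n_bins` windows ([make_windows()]); each bin
#' counts the peaks overlapping it by >= 1 bp; the profile is the mean
#' count per bin index over anchors. Anchors shorter than `n_bins` bp are
#' skipped with a warning.
#'
#' @param anchors region table of anchors.
#' @param peaks region table of peaks.
#' @param n_bins number of bins per anchor (default 100).
#' @return list with `profile` (length `n_bins`), `counts` (anchors x bins
#'   matrix) and `n_anchors` used.
#' @export
anchor_bin_profile <- function(anchors, peaks, n_bins = 100) {
  ok <- region_width(anchors) >= n_bins
  if (any(!ok)) {
    warning(sprintf("skipped %d anchor(s) shorter than %d bp", sum(!ok), n_bins))
  }
  anchors <- anchors[ok, , drop = FALSE]
  if (nrow(anchors) == 0) stop("no anchor long enough to bin")
  wins <- do.call(rbind, lapply(seq_len(nrow(anchors)), function(i) {
    w <- make_windows(anchors$chrom[i], anchors$start[i], anchors$end[i], n_bins)
    w$anchor <- i
    w
  }))
  counts <- matrix(0, nrow = nrow(anchors), ncol = n_bins)
  if (nrow(peaks) > 0) {
    ws <- wins[order(wins$chrom, wins$start, wins$end, method = "radix"), ]
    p <- overlap_pairs(ws, sort_regions(peaks[, c("chrom", "start", "end")]))
    if (nrow(p) > 0) {
      tab <- table(factor(ws$anchor[p$query_i], levels = seq_len(nrow(anchors))),
                   factor(ws$win[p$query_i], levels = seq_len(n_bins)))
      counts <- matrix(as.numeric(tab), nrow = nrow(anchors))
    }
  }
  list(profile = colMeans(counts), counts = counts, n_anchors = nrow(anchors))
}

#' Link DEGs to new loops anchored on CTCF-up B2 elements
#'
#' A new loop is a B2 new loop iff at least one anchor overlaps (>= 1 bp) a
#' `ctcf_up_b2` region. A differentially expressed gene (p below `alpha`)
#' is reported iff its promoter (TSS +/- `promoter_halfwidth`) overlaps at
#' least one anchor of a B2 new loop.
#'
#' @param degs data.frame with `gene`, `log2fc`, `p`.
#' @param genes gene table with strand and `gene` column.
#' @param loop_class classified loop table from [classify_loops()].
#' @param ctcf_up_b2 region table of CTCF-up peaks on B2 elements.
#' @param promoter_halfwidth promoter half-width in bp (default 3000).
#' @param alpha DEG p-value threshold (default 0.05).
#' @return data.frame with one row per (gene, loop, anchor side) link.
#' @export
link_deg_loops <- function(degs, genes, loop_class, ctcf_up_b2,
                           promoter_halfwidth = 3000, alpha = 0.05) {
  deg <- degs[degs$p < alpha, , drop = FALSE]
  missing <- setdiff(deg$gene, genes$gene)
  if (length(missing) > 0) {
    warning(sprintf("%d DEG(s) absent from the gene model; skipped", length(missing)))
    deg <- deg[deg$gene %in% genes$gene, , drop = FALSE]
  }
  new_loops <- loop_class[loop_class$klass == "new", , drop = FALSE]
  empty <- data.frame(gene = character(), loop_chrom = character(),
                      loop_start1 = numeric(), loop_end1 = numeric(),
                      loop_start2 = numeric(), loop_end2 = numeric(),
                      side = character(), stringsAsFactors = FALSE)
  if (nrow(new_loops) == 0 || nrow(deg) == 0) return(empty)
  b2new <- new_loops[loops_touching(new_loops, ctcf_up_b2), , drop = FALSE]
  if (nrow(b2new) == 0) return(empty)
  g <- genes[match(deg$gene, genes$gene), , drop = FALSE]
  tss <- tss_positions(g)
  prom <- data.frame(chrom = tss$chrom,
                     start = pmax(0, tss$pos - promoter_halfwidth),
                     end = tss$pos + promoter_halfwidth,
                     gene = deg$gene, stringsAsFactors = FALSE)
  prom_s <- sort_regions(prom)
  anch <- loop_anchors(b2new)
  p <- overlap_pairs(prom_s, anch[, c("chrom", "start", "end")])
  if (nrow(p) == 0) return(empty)
  out <- data.frame(
    gene = prom_s$gene[p$query_i],
    loop_chrom = anch$chrom[p$target_i],
    loop_start1 = b2new$start1[anch$loop_id[p$target_i]],
    loop_end1 = b2new$end1[anch$loop_id[p$target_i]],
    loop_start2 = b2new$start2[anch$loop_id[p$target_i]],
    loop_end2 = b2new$end2[anch$loop_id[p$target_i]],
    side = anch$side[p$target_i], stringsAsFactors = FALSE
  )
  out <- unique(out)
  rownames(out) <- NULL
  out[order(out$gene), , drop = FALSE]
}
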