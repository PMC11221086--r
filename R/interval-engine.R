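# Core interval algebra: fraction-rule intersection, merging, nearest
# distance, windowing, Jaccard. Overlap detection is delegated to IRanges;
# the reciprocal-fraction semantics (bedtools -f/-F/-e) are applied on top.

#' Construct a reciprocal-overlap rule
#'
#' Mirrors the bedtools `-f`/`-F`/`-e` convention: an overlap qualifies when
#' it covers at least `min_frac_query` of the query AND at least
#' `min_frac_target` of the target; with `either_satisfies = TRUE` the AND
#' becomes an OR. Fractions are compared with `>=`, so "overlapping >= 50%"
#' is `overlap_rule(0.5, 0.5, TRUE)`.
#'
#' @param min_frac_query,min_frac_target minimum overlap fraction of the
#'   query / target interval, each in (0, 1].
#' @param either_satisfies if `TRUE`, satisfying either fraction suffices.
#' @return object of class `overlap_rule`.
#' @export
overlap_rule <- function(min_frac_query = 0.5, min_frac_target = 0.5,
                         either_satisfies = TRUE) {
  stopifnot(min_frac_query > 0, min_frac_query <= 1,
            min_frac_target > 0, min_frac_target <= 1,
            is.logical(either_satisfies), length(either_satisfies) == 1)
  structure(list(min_frac_query = min_frac_query,
                 min_frac_target = min_frac_target,
                 either_satisfies = either_satisfies),
            class = "overlap_rule")
}

# Raw >=1bp overlap pairs between two sorted region tables.
overlap_pairs <- function(query, target) {
  out <- list()
  q_by <- split_by_chrom(query)
  t_by <- split_by_chrom(target)
  for (chrom in intersect(names(q_by), names(t_by))) {
    qi <- q_by[[chrom]]; ti <- t_by[[chrom]]
    qr <- as_iranges0(query$start[qi], query$end[qi])
    tr <- as_iranges0(target$start[ti], target$end[ti])
    hits <- IRanges::findOverlaps(qr, tr, minoverlap = 1L)
    if (length(hits) == 0) next
    qh <- S4Vectors::queryHits(hits); th <- S4Vectors::subjectHits(hits)
    ov <- pmin(query$end[qi][qh], target$end[ti][th]) -
      pmax(query$start[qi][qh], target$start[ti][th])
    out[[chrom]] <- data.frame(query_i = qi[qh], target_i = ti[th],
                               overlap_bp = ov)
  }
  if (length(out) == 0) {
    return(data.frame(query_i = integer(), target_i = integer(),
                      overlap_bp = numeric()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$query_i, res$target_i), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Intersect two region sets under a fraction rule
#'
#' Reports each (query, target) pair whose overlap satisfies the rule,
#' exactly once, with the overlap size in bp.
#'
#' @param query,target sorted region tables.
#' @param rule an [overlap_rule()].
#' @return data.frame with `query_i`, `target_i` (row indices into the
#'   inputs) and `overlap_bp`.
#' @export
region_intersect <- function(query, target, rule = overlap_rule()) {
  stopifnot(inherits(rule, "overlap_rule"))
  validate_regions(query, "query"); validate_regions(target, "target")
  stop_if_unsorted(query, "query"); stop_if_unsorted(target, "target")
  p <- overlap_pairs(query, target)
  if (nrow(p) == 0) return(p)
  ok_q <- p$overlap_bp >= rule$min_frac_query * region_width(query)[p$query_i]
  ok_t <- p$overlap_bp >= rule$min_frac_target * region_width(target)[p$target_i]
  keep <- if (rule$either_satisfies) ok_q | ok_t else ok_q & ok_t
  res <- p[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Merge overlapping regions
#'
#' Collapses overlapping (>= 1 bp) regions into disjoint components.
#' Half-open abutting regions (`[0,10)`, `[10,20)`) are NOT merged: they
#' share no base.
#'
#' @param x sorted region table.
#' @return sorted region table of disjoint components with a `n_merged`
#'   column (number of input regions in each component).
#' @export
region_merge <- function(x) {
  validate_regions(x); stop_if_unsorted(x, "x")
  if (nrow(x) == 0) {
    out <- regions(character(), numeric(), numeric()); out$n_merged <- integer()
    return(out)
  }
  out <- list()
  for (chrom in unique(x$chrom)) {
    xi <- x[x$chrom == chrom, , drop = FALSE]
    cmax <- cummax(xi$end)
    # new component where a region starts at/after the running max end
    comp <- cumsum(c(TRUE, xi$start[-1] >= cmax[-nrow(xi)]))
    out[[chrom]] <- data.frame(
      chrom = chrom,
      start = tapply(xi$start, comp, min),
      end = tapply(xi$end, comp, max),
      n_merged = as.integer(table(comp)),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  res$strand <- "."
  res <- res[, c("chrom", "start", "end", "strand", "n_merged")]
  sort_regions(res)
}

#' Distance from region midpoints to the nearest anchor point
#'
#' The distance is `min |midpoint - anchor|` over anchors on the same
#' chromosome, where the midpoint is `floor((start + end) / 2)`. Queries on
#' chromosomes with no anchor get `NA`.
#'
#' @param query region table.
#' @param anchors data.frame with `chrom` and `pos` (e.g. TSS positions
#'   from [tss_positions()]).
#' @return numeric vector of distances, one per query row.
#' @export
distance_to_nearest <- function(query, anchors) {
  stopifnot(all(c("chrom", "pos") %in% names(anchors)))
  mid <- region_midpoint(query)
  d <- rep(NA_real_, nrow(query))
  for (chrom in unique(query$chrom)) {
    a <- sort(anchors$pos[anchors$chrom == chrom])
    if (length(a) == 0) next
    qi <- which(query$chrom == chrom)
    idx <- findInterval(mid[qi], a)
    lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(a))
    d[qi] <- pmin(abs(mid[qi] - a[lo]), abs(mid[qi] - a[hi]))
  }
  d
}

#' TSS positions of a gene table
#'
#' TSS is `start` for `+` genes and `end` for `-` genes (0-based; for a
#' `-` gene the TSS base is `end - 1`, and `end` is used as the half-open
#' boundary position consistently throughout).
#'
#' @param genes gene region table with strand and `gene` columns.
#' @return data.frame with `chrom`, `pos`, `gene`.
#' @export
tss_positions <- function(genes) {
  if (!all(genes$strand %in% c("+", "-"))) stop("every gene needs strand '+' or '-'")
  data.frame(chrom = genes$chrom,
             pos = ifelse(genes$strand == "+", genes$start, genes$end),
             gene = if ("gene" %in% names(genes)) genes$gene else NA_character_,
             stringsAsFactors = FALSE)
}

#' Tile an interval into n contiguous windows
#'
#' The n windows tile `[start, end)` exactly; the first `len %% n` windows
#' are `ceiling(len/n)` bp, the rest `floor(len/n)` bp, so sizes differ by
#' at most 1 bp.
#'
#' @param chrom chromosome name.
#' @param start,end interval (0-based half-open), `end - start >= n`.
#' @param n number of windows (>= 1).
#' @return region table with a `win` index column (1..n).
#' @export
make_windows <- function(chrom, start, end, n) {
  len <- end - start
  if (n < 1) stop("n must be >= 1")
  if (len < n) {
    stop(sprintf("interval length %s < n = %d windows",
                 format(len, scientific = FALSE), n))
  }
  base <- len %/% n
  rem <- len %% n
  sizes <- rep(base, n)
  if (rem > 0) sizes[seq_len(rem)] <- base + 1
  ends <- start + cumsum(sizes)
  data.frame(chrom = chrom, start = c(start, ends[-n]), end = ends,
             win = seq_len(n), stringsAsFactors = FALSE)
}

#' Jaccard similarity of two merged region sets
#'
#' `bp` mode is intersecting bp over union bp. `element` mode counts
#' components of the merged union of both sets: a component is *matched*
#' when it contains regions from both sets (the anchor-matching rule of
#' [classify_anchors()]), and the coefficient is matched components over
#' all components.
#'
#' @param a,b merged (disjoint) region tables.
#' @param mode `"element"` or `"bp"`.
#' @return numeric in \[0, 1\].
#' @export
region_jaccard <- function(a, b, mode = c("element", "bp")) {
  mode <- match.arg(mode)
  if (nrow(a) == 0 && nrow(b) == 0) stop("Jaccard undefined: both sets empty")
  if (mode == "bp") {
    p <- overlap_pairs(sort_regions(a), sort_regions(b))
    inter <- sum(p$overlap_bp)
    uni <- sum(region_width(region_merge(sort_regions(rbind(
      a[, c("chrom", "start", "end")], b[, c("chrom", "start", "end")])))))
    return(inter / uni)
  }
  u <- region_merge(sort_regions(rbind(a[, c("chrom", "start", "end")],
                                       b[, c("chrom", "start", "end")])))
  in_a <- rep(FALSE, nrow(u)); in_b <- rep(FALSE, nrow(u))
  pa <- overlap_pairs(u, sort_regions(a)); in_a[unique(pa$query_i)] <- TRUE
  pb <- overlap_pairs(u, sort_regions(b)); in_b[unique(pb$query_i)] <- TRUE
  sum(in_a & in_b) / nrow(u)
}
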