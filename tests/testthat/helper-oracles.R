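# Independent brute-force oracles and shared fixtures. The oracles use
# plain loops over all pairs/windows and never call into the package's
# interval or scanning machinery.

# all-pairs interval intersection under the reciprocal-fraction rule
oracle_intersect <- function(query, target, min_fq, min_ft, either) {
  out <- list()
  for (i in seq_len(nrow(query))) {
    for (j in seq_len(nrow(target))) {
      if (query$chrom[i] != target$chrom[j]) next
      ov <- min(query$end[i], target$end[j]) - max(query$start[i], target$start[j])
      if (ov <= 0) next
      ok_q <- ov >= min_fq * (query$end[i] - query$start[i])
      ok_t <- ov >= min_ft * (target$end[j] - target$start[j])
      ok <- if (either) ok_q || ok_t else ok_q && ok_t
      if (ok) out[[length(out) + 1]] <- c(i, j, ov)
    }
  }
  if (length(out) == 0) {
    return(data.frame(query_i = integer(), target_i = integer(),
                      overlap_bp = numeric()))
  }
  m <- do.call(rbind, out)
  res <- data.frame(query_i = m[, 1], target_i = m[, 2], overlap_bp = m[, 3])
  res[order(res$query_i, res$target_i), ]
}

# covered-bp of a region set on one small chromosome via a per-bp bitmap
oracle_covered_bp <- function(x, chrom_len) {
  hit <- logical(chrom_len)
  for (i in seq_len(nrow(x))) {
    if (x$end[i] > x$start[i]) hit[(x$start[i] + 1):x$end[i]] <- TRUE
  }
  sum(hit)
}

# min distance from each region midpoint to any anchor on its chromosome
oracle_distance <- function(query, anchors) {
  vapply(seq_len(nrow(query)), function(i) {
    mid <- floor((query$start[i] + query$end[i]) / 2)
    a <- anchors$pos[anchors$chrom == query$chrom[i]]
    if (length(a) == 0) return(NA_real_)
    min(abs(mid - a))
  }, 0)
}

# per-bin peak counts for one anchor tiled into n bins (loop over bins
# and peaks; the remainder convention is recomputed from first principles)
oracle_bin_counts <- function(anchor, peaks, n_bins) {
  len <- anchor$end - anchor$start
  base <- len %/% n_bins; rem <- len %% n_bins
  sizes <- rep(base, n_bins); if (rem > 0) sizes[seq_len(rem)] <- base + 1
  ends <- anchor$start + cumsum(sizes)
  starts <- c(anchor$start, ends[-n_bins])
  vapply(seq_len(n_bins), function(b) {
    n <- 0
    for (j in seq_len(nrow(peaks))) {
      if (peaks$chrom[j] != anchor$chrom) next
      if (min(ends[b], peaks$end[j]) - max(starts[b], peaks$start[j]) > 0) n <- n + 1
    }
    n
  }, 0)
}

# exhaustive best PWM hit: score every window on both strands directly
# from the probability matrix
oracle_scan <- function(probs, background, sequence, threshold) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  b <- strsplit(toupper(sequence), "")[[1]]
  w <- ncol(probs)
  best <- NULL
  for (off in 0:(length(b) - w)) {
    for (strand in c("+", "-")) {
      win <- b[(off + 1):(off + w)]
      if (strand == "-") win <- rev(unname(comp[win]))
      if (any(!win %in% c("A", "C", "G", "T"))) next
      sc <- 0
      for (j in seq_len(w)) {
        sc <- sc + unname(log2(probs[win[j], j] / background[j_base(win[j])]))
      }
      cand <- list(score = sc, offset = off, strand = strand)
      if (is.null(best) || sc > best$score ||
          (sc == best$score && (off < best$offset ||
                                (off == best$offset && strand == "+" &&
                                   best$strand == "-")))) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    return(list(best_score = NA_real_, strand = NA_character_,
                offset = NA_integer_, passes = FALSE))
  }
  list(best_score = best$score, strand = best$strand,
       offset = as.integer(best$offset), passes = best$score >= threshold)
}
j_base <- function(b) match(b, c("A", "C", "G", "T"))

# two-sided Fisher p by direct enumeration of all tables with the observed
# margins, probabilities from lchoose (1e-7 relative tie guard)
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0, k - n); hi <- min(k, m)
  logp <- function(x) {
    lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  }
  p_obs <- exp(logp(a))
  xs <- lo:hi
  sum(exp(logp(xs))[exp(logp(xs)) <= p_obs * (1 + 1e-7)])
}

# random sorted region table on small chromosomes
random_regions <- function(n, chroms = c("chrA", "chrB"), len = 1e6,
                           min_w = 5, max_w = 2000) {
  w <- sample(min_w:max_w, n, replace = TRUE)
  s <- sample(0:(len - max_w - 1), n, replace = TRUE)
  sort_regions(data.frame(chrom = sample(chroms, n, replace = TRUE),
                          start = s, end = s + w, strand = ".",
                          stringsAsFactors = FALSE))
}

# small, fast synthetic configuration for unit tests
tiny_config <- function(seed = 11, chrom_sizes = c(chrA = 4e5, chrB = 4e5),
                        n_te = 300, ...) {
  synthetic_config(
    seed = seed,
    chrom_sizes = chrom_sizes,
    n_te = n_te, n_genes = 40, gene_len = c(2000, 8000),
    n_degs = 12, n_linked_genes = 5,
    n_peaks = 400, n_ctcf_peaks = 200, n_ctcf_up_b2 = 40,
    n_loops = 60, anchor_width = 2000, loop_span = c(2e4, 1e5),
    n_dmr = 10, n_dmr_hyper = 4, n_null_cpg = 5000,
    ...
  )
}

# the full-size study bundle, generated once per test run
default_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(synthetic_config())
    cache
  }
})
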