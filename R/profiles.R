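# Aggregate signal over region sets in the scale-regions convention:
# fixed-size flank bins, a region body split into equal-as-possible bins,
# coverage-weighted mean signal per bin.

#' Build a scaled-body signal matrix over regions
#'
#' Each row is one region read 5' to 3' (minus-strand rows are reversed):
#' `flank_up / bin_size` fixed upstream bins, `body_bins` bins tiling the
#' region body ([make_windows()]), and `flank_down / bin_size` downstream
#' bins. A bin's value is the coverage-weighted mean of the track over the
#' bin; positions absent from the track contribute 0. Bins clipped at
#' chromosome bounds (when `chrom_sizes` is given) contribute 0 over the
#' clipped part, with a warning.
#'
#' @param track bedGraph-style region table with a `value` column,
#'   non-overlapping within itself.
#' @param x region table (strand honoured when present).
#' @param flank_up,flank_down flank sizes in bp (default 1000 each); must
#'   be multiples of `bin_size`.
#' @param body_bins number of body bins (default 100).
#' @param bin_size flank bin size in bp (default 10).
#' @param skip_zeros drop regions whose every bin is 0 (default `FALSE`).
#' @param chrom_sizes optional named vector of chromosome lengths used for
#'   clipping.
#' @return object of class `signal_matrix`: `values` (regions x bins),
#'   `region_i` (row indices of `x` retained), bin bookkeeping fields.
#' @export
compute_matrix <- function(track, x, flank_up = 1000, flank_down = 1000,
                           body_bins = 100, bin_size = 10,
                           skip_zeros = FALSE, chrom_sizes = NULL) {
  stopifnot("value" %in% names(track), bin_size >= 1,
            flank_up %% bin_size == 0, flank_down %% bin_size == 0)
  n_up <- flank_up %/% bin_size
  n_down <- flank_down %/% bin_size
  n_bins <- n_up + body_bins + n_down
  strand <- if ("strand" %in% names(x)) x$strand else rep(".", nrow(x))
  bins <- vector("list", nrow(x))
  clipped <- FALSE
  for (i in seq_len(nrow(x))) {
    minus <- strand[i] == "-"
    a <- if (minus) flank_down else flank_up   # left (genomic) flank size
    b <- if (minus) flank_up else flank_down
    left <- if (a > 0) {
      s <- x$start[i] - seq(a, bin_size, by = -bin_size)
      data.frame(start = s, end = s + bin_size)
    } else NULL
    body <- make_windows(x$chrom[i], x$start[i], x$end[i], body_bins)
    right <- if (b > 0) {
      s <- x$end[i] + seq(0, b - bin_size, by = bin_size)
      data.frame(start = s, end = s + bin_size)
    } else NULL
    bb <- rbind(
      if (!is.null(left)) data.frame(start = left$start, end = left$end),
      data.frame(start = body$start, end = body$end),
      if (!is.null(right)) data.frame(start = right$start, end = right$end)
    )
    bb$chrom <- x$chrom[i]
    bb$region <- i
    bb$bin <- if (minus) rev(seq_len(n_bins)) else seq_len(n_bins)
    bins[[i]] <- bb
  }
  allb <- do.call(rbind, bins)
  allb$width <- allb$end - allb$start
  # clip at [0, chrom size]; clipped bp count as 0 signal
  lim <- if (is.null(chrom_sizes)) rep(Inf, nrow(allb)) else
    unname(chrom_sizes[allb$chrom])
  cs <- pmax(allb$start, 0); ce <- pmin(allb$end, lim)
  if (any(cs > allb$start | ce < allb$end)) {
    warning("some bins extend past chromosome bounds; clipped (signal 0)")
    clipped <- TRUE
  }
  vals <- matrix(0, nrow = nrow(x), ncol = n_bins)
  ok <- ce > cs
  if (any(ok) && nrow(track) > 0) {
    q <- data.frame(chrom = allb$chrom[ok], start = cs[ok], end = ce[ok])
    ord <- order(q$chrom, q$start, q$end, method = "radix")
    qs <- q[ord, , drop = FALSE]
    p <- overlap_pairs(qs, sort_regions(track[, c("chrom", "start", "end", "value")]))
    if (nrow(p) > 0) {
      ts <- sort_regions(track[, c("chrom", "start", "end", "value")])
      wsum <- tapply(p$overlap_bp * ts$value[p$target_i], p$query_i, sum)
      rows_ok <- which(ok)[ord]
      hit_rows <- rows_ok[as.integer(names(wsum))]
      vals[cbind(allb$region[hit_rows], allb$bin[hit_rows])] <-
        as.numeric(wsum) / allb$width[hit_rows]
    }
  }
  region_i <- seq_len(nrow(x))
  if (skip_zeros) {
    keep <- rowSums(vals != 0) > 0
    vals <- vals[keep, , drop = FALSE]
    region_i <- region_i[keep]
  }
  structure(list(values = vals, region_i = region_i,
                 n_flank_bins_up = n_up, n_body_bins = body_bins,
                 n_flank_bins_down = n_down, bin_size = bin_size,
                 clipped = clipped),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("signal_matrix: %d regions x %d bins (%d up + %d body + %d down)\n",
              nrow(x$values), ncol(x$values), x$n_flank_bins_up,
              x$n_body_bins, x$n_flank_bins_down))
  invisible(x)
}

#' Mean signal profile of a signal matrix
#' @param m a [compute_matrix()] result with at least one region.
#' @return numeric vector of per-bin column means.
#' @export
mean_profile <- function(m) {
  stopifnot(inherits(m, "signal_matrix"))
  if (nrow(m$values) == 0) stop("empty signal matrix")
  colMeans(m$values)
}
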