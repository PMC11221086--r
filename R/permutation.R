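# Resample-from-universe permutation tests for region-set association.

#' Permutation test of region-set association by universe resampling
#'
#' Each iteration draws `|query|` regions uniformly without replacement
#' from the universe and recomputes the statistic, giving a null
#' distribution for the observed query. Statistics: `num_overlaps` — the
#' number of sampled regions overlapping (>= 1 bp) at least one feature;
#' `mean_distance` — the mean distance from sampled-region midpoints to
#' the nearest feature midpoint. The empirical p-value is +1-smoothed:
#' `(1 + #{null as-or-more-extreme}) / (n_iter + 1)`, so it is never 0.
#'
#' @param query region table; must be a coordinate-subset of `universe`.
#' @param universe region table to resample from.
#' @param features region table of features.
#' @param statistic `"num_overlaps"` or `"mean_distance"`.
#' @param n_iter number of permutations (default 200).
#' @param alternative `"greater"` or `"less"`.
#' @param seed optional integer seed; results are deterministic given it.
#' @return object of class `perm_test`: `statistic`, `observed`,
#'   `null_mean`, `null_sd`, `z`, `p_empirical`, `n_iter`, `alternative`,
#'   `seed`, and the `null` vector.
#' @export
perm_test <- function(query, universe, features,
                      statistic = c("num_overlaps", "mean_distance"),
                      n_iter = 200, alternative = c("greater", "less"),
                      seed = NULL) {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  stopifnot(n_iter >= 1, nrow(query) >= 1)
  uk <- region_key(universe); qk <- region_key(query)
  if (!all(qk %in% uk)) stop("query must be a coordinate-subset of the universe")
  q_idx <- match(qk, uk)
  n_u <- nrow(universe); n_q <- nrow(query)
  stopifnot(n_u >= n_q)
  feats <- sort_regions(features[, c("chrom", "start", "end"), drop = FALSE])
  if (statistic == "num_overlaps") {
    per_region <- rep(0, n_u)
    if (nrow(feats) > 0) {
      us <- sort_regions(cbind(universe[, c("chrom", "start", "end")],
                               idx = seq_len(n_u)))
      p <- overlap_pairs(us, feats)
      per_region[us$idx[unique(p$query_i)]] <- 1
    }
    stat_fun <- function(idx) sum(per_region[idx])
  } else {
    if (nrow(feats) == 0) stop("mean_distance needs a non-empty feature set")
    anchors <- data.frame(chrom = feats$chrom, pos = region_midpoint(feats))
    per_region <- distance_to_nearest(universe, anchors)
    stat_fun <- function(idx) mean(per_region[idx])
  }
  observed <- stat_fun(q_idx)
  if (!is.null(seed)) set.seed(seed)
  null <- vapply(seq_len(n_iter),
                 function(i) stat_fun(sample.int(n_u, n_q)), 0)
  extreme <- if (alternative == "greater") sum(null >= observed) else sum(null <= observed)
  null_sd <- stats::sd(null)
  structure(list(
    statistic = statistic, observed = observed,
    null_mean = mean(null), null_sd = null_sd,
    z = if (!is.na(null_sd) && null_sd > 0) (observed - mean(null)) / null_sd else NA_real_,
    obs_over_expected = if (mean(null) != 0) observed / mean(null) else NA_real_,
    p_empirical = (1 + extreme) / (n_iter + 1),
    n_iter = n_iter, alternative = alternative,
    seed = if (is.null(seed)) NA_integer_ else seed,
    null = null
  ), class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "perm_test (%s, %s): observed %.4g, null %.4g +/- %.4g, z %.3g, p %.4g (%d iters)\n",
    x$statistic, x$alternative, x$observed, x$null_mean, x$null_sd,
    x$z, x$p_empirical, x$n_iter))
  invisible(x)
}
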