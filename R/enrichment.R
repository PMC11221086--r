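# TE-hierarchy and genomic-annotation enrichment of differential region
# sets against a background, by element count and by cumulative length.

#' Fisher's exact test on a 2x2 table
#'
#' Returns the plain sample odds ratio `(a*d)/(b*c)` (with 0-cells giving
#' `Inf`/`0`) and the two-sided exact p-value: the sum of hypergeometric
#' probabilities of tables, at the observed margins, whose probability does
#' not exceed the observed table's (up to the standard 1e-7 relative
#' floating-point tie guard).
#'
#' @param a,b,c,d non-negative integer cells, rows (a, b) and (c, d).
#' @return list with `odds_ratio` and `p`.
#' @export
fisher_test <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers")
  }
  if (sum(cells) == 0) stop("all cells are zero: test undefined")
  or <- if (b * c > 0) (a * d) / (b * c) else if (a * d > 0) Inf else NaN
  p <- stats::fisher.test(matrix(cells, nrow = 2, byrow = TRUE))$p.value
  list(odds_ratio = or, p = min(p, 1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with enforced monotonicity, capped at 1, order
#' preserved (a validating wrapper around `stats::p.adjust`).
#'
#' @param p numeric p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

region_key <- function(x) {
  paste0(x$chrom, ":", format(x$start, trim = TRUE, scientific = FALSE), "-",
         format(x$end, trim = TRUE, scientific = FALSE))
}

te_level_field <- function(level) {
  switch(level, te_class = "te_class", sine_family = "te_family",
         b2_subtype = "te_subtype", stop(sprintf("unknown level '%s'", level)))
}

te_restrict <- function(te, level) {
  switch(level,
         te_class = te,
         sine_family = te[te$te_class == "SINE", , drop = FALSE],
         b2_subtype = te[te$te_family == "B2", , drop = FALSE])
}

#' TE-hierarchy enrichment of a differential region set
#'
#' For each category at the chosen hierarchy level, builds a 2x2 table of
#' foreground versus background regions and applies Fisher's exact test with
#' Benjamini-Hochberg adjustment across the level's categories.
#'
#' In `count` mode the cells are numbers of regions overlapping (per the
#' rule) at least one element of the category versus not, in the foreground
#' and in the full background; a region overlapping several elements of one
#' category counts once, and once per category when it spans categories.
#' In `length` mode the cells are cumulative bp of the distinct TE elements
#' of the category hit by foreground (resp. background) regions, against
#' the bp of hit elements of the level's other categories; because bp are
#' not independent trials, fold enrichment is the primary length-mode
#' readout and the p-value is secondary.
#'
#' @param diff_regions foreground region table (e.g. the up set); must be a
#'   coordinate-subset of `all_regions`.
#' @param all_regions background region table (all detected peaks).
#' @param te TE annotation table (from [read_te_annotation()]).
#' @param rule an [overlap_rule()]; default reciprocal 0.5/0.5, either.
#' @param level `"te_class"`, `"sine_family"` (SINE families only) or
#'   `"b2_subtype"` (B2 subtypes only).
#' @param mode `"count"` or `"length"`.
#' @return data.frame with one row per category: level, category, mode, the
#'   four table cells, `fold_enrichment`, `p`, `p_adj`.
#' @export
enrich_te <- function(diff_regions, all_regions, te, rule = overlap_rule(),
                      level = c("te_class", "sine_family", "b2_subtype"),
                      mode = c("count", "length")) {
  level <- match.arg(level); mode <- match.arg(mode)
  diff_regions <- sort_regions(diff_regions)
  all_regions <- sort_regions(all_regions)
  if (!all(region_key(diff_regions) %in% region_key(all_regions))) {
    stop("foreground must be a coordinate-subset of the background")
  }
  te <- sort_regions(te_restrict(te, level))
  field <- te_level_field(level)
  categories <- sort(unique(te[[field]]))
  fg_keys <- region_key(diff_regions)
  is_fg <- region_key(all_regions) %in% fg_keys
  hits <- region_intersect(all_regions, te, rule)
  n_fg <- nrow(diff_regions); n_bg <- nrow(all_regions)
  rows <- lapply(categories, function(cat) {
    h <- hits[te[[field]][hits$target_i] == cat, , drop = FALSE]
    if (mode == "count") {
      reg <- unique(h$query_i)
      a <- sum(is_fg[reg]); b <- n_fg - a
      cc <- length(reg); d <- n_bg - cc
    } else {
      elems_any <- unique(hits$target_i[is_fg[hits$query_i]])
      a <- round(sum(region_width(te)[intersect(elems_any, unique(h$target_i))]))
      b <- round(sum(region_width(te)[setdiff(elems_any, unique(h$target_i))]))
      elems_bg <- unique(hits$target_i)
      cc <- round(sum(region_width(te)[intersect(elems_bg, unique(h$target_i))]))
      d <- round(sum(region_width(te)[setdiff(elems_bg, unique(h$target_i))]))
    }
    fe <- if ((a + b) > 0 && (cc + d) > 0 && cc > 0) {
      (a / (a + b)) / (cc / (cc + d))
    } else NA_real_
    p <- if (a + b + cc + d > 0) fisher_test(a, b, cc, d)$p else NA_real_
    data.frame(level = level, category = cat, mode = mode,
               observed_in = a, observed_out = b,
               background_in = cc, background_out = d,
               fold_enrichment = fe, p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(ifelse(is.na(res$p), 1, res$p))
  res
}

#' Annotate regions as promoter / gene body / intergenic
#'
#' Promoters are `[TSS - w, TSS + w)` with strand-aware TSS (gene start for
#' `+`, gene end for `-`). Precedence: promoter > gene_body > intergenic;
#' a region overlapping any promoter window (>= 1 bp) is a promoter region
#' even if it also lies in a gene body.
#'
#' @param x region table to annotate.
#' @param genes gene table with strand (see [read_genes()]).
#' @param promoter_halfwidth promoter half-width in bp (default 3000).
#' @return character vector of labels, one per region of `x`.
#' @export
annotate_regions <- function(x, genes, promoter_halfwidth = 3000) {
  if (!all(genes$strand %in% c("+", "-"))) stop("every gene needs strand '+' or '-'")
  x <- validate_regions(x)
  tss <- tss_positions(genes)
  prom <- data.frame(chrom = tss$chrom,
                     start = pmax(0, tss$pos - promoter_halfwidth),
                     end = tss$pos + promoter_halfwidth,
                     stringsAsFactors = FALSE)
  xs <- sort_regions(x[, c("chrom", "start", "end")])
  # row i of xs is original row o[i]
  o <- order(x$chrom, x$start, x$end, method = "radix")
  labels <- rep("intergenic", nrow(x))
  p_hit <- overlap_pairs(xs, sort_regions(prom))
  g_hit <- overlap_pairs(xs, sort_regions(genes[, c("chrom", "start", "end")]))
  in_gene <- seq_len(nrow(x)) %in% o[unique(g_hit$query_i)]
  labels[in_gene] <- "gene_body"
  in_prom <- seq_len(nrow(x)) %in% o[unique(p_hit$query_i)]
  labels[in_prom] <- "promoter"
  labels
}

#' Genomic-annotation enrichment (promoter / gene body / intergenic)
#'
#' Fisher enrichment of the foreground's annotation composition against the
#' background's, BH-adjusted across the three labels.
#'
#' @param foreground,background region tables; background must be non-empty.
#' @param genes gene table with strand.
#' @param promoter_halfwidth promoter half-width in bp.
#' @return data.frame as in [enrich_te()] with level `genomic_annotation`.
#' @export
enrich_annotation <- function(foreground, background, genes,
                              promoter_halfwidth = 3000) {
  if (nrow(background) == 0) stop("empty background")
  fg_lab <- annotate_regions(foreground, genes, promoter_halfwidth)
  bg_lab <- annotate_regions(background, genes, promoter_halfwidth)
  labs <- c("promoter", "gene_body", "intergenic")
  rows <- lapply(labs, function(L) {
    a <- sum(fg_lab == L); b <- length(fg_lab) - a
    cc <- sum(bg_lab == L); d <- length(bg_lab) - cc
    fe <- if (cc > 0 && (a + b) > 0) (a / (a + b)) / (cc / (cc + d)) else NA_real_
    data.frame(level = "genomic_annotation", category = L, mode = "count",
               observed_in = a, observed_out = b, background_in = cc,
               background_out = d, fold_enrichment = fe,
               p = fisher_test(a, b, cc, d)$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(res$p)
  res
}
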