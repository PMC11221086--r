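# CpG coverage filtering, DMR candidate selection / grouping / filtering,
# and quadrant integration of methylation with accessibility.

make_cpg <- function(chrom, pos, wt_beta, ko_beta, cov = 10) {
  n <- length(pos)
  chrom <- rep_len(chrom, n)
  samples <- c("w1", "w2", "k1", "k2")
  groups <- c(w1 = "WT", w2 = "WT", k1 = "KO", k2 = "KO")
  total <- matrix(cov, n, 4, dimnames = list(NULL, samples))
  meth <- cbind(round(wt_beta * cov), round(wt_beta * cov),
                round(ko_beta * cov), round(ko_beta * cov))
  colnames(meth) <- samples
  cpg_table(chrom, pos, matrix(as.integer(meth), n, 4, dimnames = list(NULL, samples)),
            total, groups)
}

test_that("coverage filter requires >= 2 reads in >= 1 sample per group", {
  samples <- c("w1", "w2", "k1", "k2")
  groups <- c(w1 = "WT", w2 = "WT", k1 = "KO", k2 = "KO")
  total <- matrix(c(3, 0, 0, 1,    # KO max 1 -> dropped
                    2, 0, 0, 2,    # retained
                    1, 1, 5, 5),   # WT max 1 -> dropped
                  nrow = 3, byrow = TRUE, dimnames = list(NULL, samples))
  meth <- matrix(0L, 3, 4, dimnames = list(NULL, samples))
  x <- cpg_table(rep("chr1", 3), c(10, 20, 30), meth,
                 matrix(as.integer(total), 3, 4, dimnames = list(NULL, samples)),
                 groups)
  kept <- filter_cpgs(x)
  expect_equal(kept$pos, 20)
  expect_equal(filter_cpgs(kept)$pos, kept$pos)  # idempotent
})

test_that("empty input passes through the filter", {
  samples <- c("w1", "k1")
  x <- cpg_table(character(), numeric(),
                 matrix(0L, 0, 2, dimnames = list(NULL, samples)),
                 matrix(0L, 0, 2, dimnames = list(NULL, samples)),
                 c(w1 = "WT", k1 = "KO"))
  expect_equal(length(filter_cpgs(x)$pos), 0)
})

# 500 null CpGs (d = 0) plus planted clusters at d = -0.3; the 1% lower
# quantile falls between the planted and null values, so exactly the
# planted CpGs are candidates
null_plus_cluster <- function(cluster_pos, extra_pos = numeric(),
                              extra_d = numeric()) {
  null_pos <- seq(100000, by = 1000, length.out = 500)
  pos <- c(cluster_pos, extra_pos, null_pos)
  ko <- c(rep(0.5, length(cluster_pos)), 0.8 + extra_d, rep(0.8, 500))
  wt <- rep(0.8, length(pos))
  make_cpg("chr1", pos, wt, ko)
}

test_that("a planted 6-CpG hypo cluster yields exactly one hypo DMR", {
  x <- null_plus_cluster(seq(5000, by = 100, length.out = 6))
  d <- call_dmrs(x)
  expect_equal(nrow(d), 1)
  expect_equal(d$status, "hypo")
  expect_equal(d$n_cpg, 6)
  expect_equal(d$start, 5000)
  expect_equal(d$end, 5501)
  expect_equal(d$mean_diff, -0.3, tolerance = 1e-9)
})

test_that("candidate clusters split at gaps above maxGap", {
  # two 3-CpG clusters whose boundary CpGs are 301 bp apart
  x <- null_plus_cluster(c(5000, 5100, 5200, 5501, 5601, 5701))
  d <- call_dmrs(x, max_gap = 300)
  expect_equal(nrow(d), 2)
  # at 300 bp they merge into one region
  x2 <- null_plus_cluster(c(5000, 5100, 5200, 5500, 5600, 5700))
  expect_equal(nrow(call_dmrs(x2, max_gap = 300)), 1)
})

test_that("clusters below min_cpg are not reported", {
  x <- null_plus_cluster(c(5000, 5100))
  expect_equal(nrow(call_dmrs(x, min_cpg = 3)), 0)
})

test_that("DMRs are excluded from sex chromosomes by default", {
  null_pos <- seq(100000, by = 1000, length.out = 500)
  pos <- c(seq(5000, by = 100, length.out = 6), null_pos)
  ko <- c(rep(0.5, 6), rep(0.8, 500))
  x <- make_cpg(c(rep("chrX", 6), rep("chr1", 500)), pos, rep(0.8, 506), ko)
  expect_equal(nrow(call_dmrs(x)), 0)
  expect_equal(nrow(call_dmrs(x, autosomes = "chrX")), 1)
})

test_that("too few CpGs is an error (quantiles unstable)", {
  x <- make_cpg("chr1", c(10, 20, 30), rep(0.8, 3), rep(0.5, 3))
  expect_error(call_dmrs(x), "fewer than 10")
})

test_that("swapping group labels negates mean_diff and swaps hypo/hyper", {
  x <- null_plus_cluster(seq(5000, by = 100, length.out = 6))
  flipped <- x
  flipped$groups <- stats::setNames(
    ifelse(x$groups == "WT", "KO", "WT"), names(x$groups))
  d1 <- call_dmrs(x)
  d2 <- call_dmrs(flipped)
  expect_equal(d2$mean_diff, -d1$mean_diff)
  expect_equal(d2$status, "hyper")
  expect_equal(d2[c("chrom", "start", "end", "n_cpg")],
               d1[c("chrom", "start", "end", "n_cpg")])
})

test_that("DMR output intervals are disjoint and sorted", {
  # 11 planted CpGs exceed the default 1% tail, so widen the quantile
  # cutoff to keep all of them candidates
  x <- null_plus_cluster(c(seq(5000, by = 100, length.out = 6),
                           seq(9000, by = 50, length.out = 5)))
  d <- call_dmrs(x, q_low = 0.03)
  expect_equal(nrow(d), 2)
  expect_true(is_sorted_regions(d))
  expect_true(all(d$start[-1] >= d$end[-nrow(d)]))
})

test_that("quadrants follow the sign convention and B2 x Q4 Fisher matches the oracle", {
  dmrs <- sort_regions(data.frame(
    chrom = "chr1", start = seq(1000, by = 5000, length.out = 20),
    end = seq(1000, by = 5000, length.out = 20) + 200, strand = ".",
    n_cpg = 5, mean_diff = rep(c(-0.3, 0.25), 10), avg_meth = 0.5,
    status = rep(c("hypo", "hyper"), 10), stringsAsFactors = FALSE))
  atac <- dmrs[, c("chrom", "start", "end", "strand")]
  atac$log2fc <- rep(c(1.2, 1.2, -1.1, -1.1), 5)
  atac$fdr <- 0.01
  atac$direction <- classify_direction(atac$log2fc, atac$fdr)
  # B2 elements under the first 8 regions
  b2 <- sort_regions(regions("chr1", dmrs$start[1:8] - 10, dmrs$end[1:8] + 10))
  q <- quadrant_integration(dmrs, atac, b2)
  expect_equal(nrow(q$pairs), 20)
  want_quad <- ifelse(q$pairs$log2fc > 0, ifelse(q$pairs$mean_diff >= 0, 1, 4),
                      ifelse(q$pairs$mean_diff >= 0, 2, 3))
  expect_equal(q$pairs$quadrant, want_quad)
  a <- sum(q$pairs$is_b2 & q$pairs$quadrant == 4)
  b <- sum(q$pairs$is_b2 & q$pairs$quadrant != 4)
  cc <- sum(!q$pairs$is_b2 & q$pairs$quadrant == 4)
  d <- sum(!q$pairs$is_b2 & q$pairs$quadrant != 4)
  expect_equal(q$fisher$p, oracle_fisher_p(a, b, cc, d), tolerance = 1e-12)
})

test_that("single-quadrant pair sets are classified correctly", {
  dmr1 <- data.frame(chrom = "chr1", start = 100, end = 300, strand = ".",
                     n_cpg = 3, mean_diff = -0.2, avg_meth = 0.5,
                     status = "hypo", stringsAsFactors = FALSE)
  mk_atac <- function(lfc) {
    data.frame(chrom = "chr1", start = 150, end = 400, strand = ".",
               log2fc = lfc, fdr = 0.01,
               direction = classify_direction(lfc, 0.01),
               stringsAsFactors = FALSE)
  }
  q4 <- quadrant_integration(dmr1, mk_atac(1.0), regions("chr1", 0, 10))
  expect_equal(q4$pairs$quadrant, 4)
  dmr1$mean_diff <- 0.2
  q1 <- quadrant_integration(dmr1, mk_atac(1.0), regions("chr1", 0, 10))
  expect_equal(q1$pairs$quadrant, 1)
  expect_warning(
    quadrant_integration(dmr1, mk_atac(1.0)[0, ], regions("chr1", 0, 10)),
    "no overlapping")
})
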