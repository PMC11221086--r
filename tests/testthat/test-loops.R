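# Anchor genotype comparison, loop classification, motif orientation,
# binned anchor profiles, and DEG-loop linkage.

test_that("hand-enumerated anchor case gives NLA=LLA=ULA=1 and Jaccard 1/3", {
  wt <- loops("chr1", 0, 10000, 20000, 30000, genotype = "WT")
  ko <- loops("chr1", 0, 10000, 40000, 50000, genotype = "KO")
  cls <- classify_anchors(wt, ko)
  expect_equal(nrow(cls$nla), 1)
  expect_equal(nrow(cls$lla), 1)
  expect_equal(nrow(cls$ula), 1)
  expect_equal(cls$jaccard, 1 / 3)
  expect_equal(cls$nla$start, 40000)
  expect_equal(cls$lla$start, 20000)
})

test_that("identical and disjoint loop sets give the extreme Jaccard values", {
  wt <- loops("chr1", c(0, 100000), c(10000, 110000),
              c(20000, 300000), c(30000, 310000), "WT")
  expect_equal(classify_anchors(wt, wt)$jaccard, 1)
  expect_equal(nrow(classify_anchors(wt, wt)$nla), 0)
  ko <- loops("chr1", 500000, 510000, 600000, 610000, "KO")
  cls <- classify_anchors(wt, ko)
  expect_equal(nrow(cls$ula), 0)
  expect_equal(cls$jaccard, 0)
  expect_error(classify_anchors(wt[0, ], ko), "at least one loop")
})

random_loops <- function(n, genotype, seed) {
  set.seed(seed)
  c1 <- sample(seq(5000, 4e5, by = 100), n)
  span <- sample(seq(2e4, 1e5, by = 500), n, replace = TRUE)
  loops("chr1", c1, c1 + 4000, c1 + span, c1 + span + 4000, genotype)
}

test_that("swapping genotypes swaps NLA/LLA and preserves ULA and Jaccard", {
  wt <- random_loops(30, "WT", 1)
  ko <- random_loops(30, "KO", 2)
  a <- classify_anchors(wt, ko)
  b <- classify_anchors(ko, wt)
  expect_equal(a$nla[, c("chrom", "start", "end")],
               b$lla[, c("chrom", "start", "end")])
  expect_equal(a$lla[, c("chrom", "start", "end")],
               b$nla[, c("chrom", "start", "end")])
  expect_equal(a$ula[, c("chrom", "start", "end")],
               b$ula[, c("chrom", "start", "end")])
  expect_equal(a$jaccard, b$jaccard)
})

test_that("every KO loop is classified exactly once as new or unchanged", {
  for (seed in 1:5) {
    wt <- random_loops(25, "WT", seed)
    ko <- random_loops(25, "KO", seed + 100)
    cls <- classify_anchors(wt, ko)
    lc <- classify_loops(wt, ko, cls)
    ko_cls <- lc[lc$genotype == "KO", ]
    expect_equal(nrow(ko_cls), nrow(ko))
    expect_true(all(ko_cls$klass %in% c("new", "unchanged")))
    wt_cls <- lc[lc$genotype == "WT", ]
    expect_true(all(wt_cls$klass %in% c("lost", "retained")))
  }
})

test_that("loop classes follow anchor membership in constructed cases", {
  wt <- loops("chr1", c(0, 100000), c(10000, 110000),
              c(20000, 200000), c(30000, 210000), "WT")
  # KO shares loop 1 exactly; loop 2 has one brand-new anchor
  ko <- loops("chr1", c(0, 100000), c(10000, 110000),
              c(20000, 400000), c(30000, 410000), "KO")
  cls <- classify_anchors(wt, ko)
  lc <- classify_loops(wt, ko, cls)
  ko_cls <- lc[lc$genotype == "KO", ]
  expect_equal(ko_cls$klass[ko_cls$start2 == 400000], "new")
  expect_equal(ko_cls$klass[ko_cls$start2 == 20000], "unchanged")
})

test_that("orientation truth table covers all strand combinations", {
  lp <- loops("chr1", rep(0, 5), rep(1000, 5),
              seq(50000, 54000, by = 1000), seq(51000, 55000, by = 1000), "KO")
  mk_hits <- function(strand, passes) {
    data.frame(best_score = 10, strand = strand, offset = 0L, passes = passes)
  }
  left <- mk_hits(c("+", "-", "+", "-", "+"), c(TRUE, TRUE, TRUE, TRUE, FALSE))
  right <- mk_hits(c("-", "+", "+", "-", "-"), TRUE)
  o <- orient_loops(lp, left, right)
  expect_equal(o$calls$orientation,
               c("convergent", "divergent", "tandem", "tandem", "unclassified"))
  s <- o$summary
  expect_equal(s$convergent + s$divergent + s$tandem, 1)
  expect_equal(s$n_unclassified, 1)
})

test_that("anchor bin profiles match degenerate cases and the per-bin oracle", {
  anchor <- regions("chr1", 1000, 2000)
  full <- regions("chr1", 0, 5000)
  p <- anchor_bin_profile(anchor, full, n_bins = 10)
  expect_equal(p$profile, rep(1, 10))
  p0 <- anchor_bin_profile(anchor, full[0, ], n_bins = 10)
  expect_equal(p0$profile, rep(0, 10))
  set.seed(42)
  for (rep in 1:10) {
    anchors <- random_regions(8, chroms = "chrA", len = 1e5,
                              min_w = 300, max_w = 3000)
    peaks <- random_regions(50, chroms = "chrA", len = 1e5,
                            min_w = 20, max_w = 800)
    got <- anchor_bin_profile(anchors, peaks, n_bins = 20)
    want <- t(vapply(seq_len(nrow(anchors)), function(i) {
      oracle_bin_counts(anchors[i, ], peaks, 20)
    }, numeric(20)))
    expect_equal(got$counts, want)
    expect_equal(got$profile, colMeans(want))
  }
})

test_that("bin profiles are additive over disjoint peak sets", {
  set.seed(3)
  anchors <- random_regions(6, chroms = "chrA", len = 5e4,
                            min_w = 500, max_w = 2000)
  peaks <- random_regions(40, chroms = "chrA", len = 5e4,
                          min_w = 10, max_w = 300)
  p_all <- anchor_bin_profile(anchors, peaks, 25)$profile
  p_a <- anchor_bin_profile(anchors, peaks[1:20, ], 25)$profile
  p_b <- anchor_bin_profile(anchors, peaks[21:40, ], 25)$profile
  expect_equal(p_all, p_a + p_b)
})

test_that("short anchors are skipped with a warning", {
  anchors <- regions("chr1", c(0, 5000), c(50, 15000))
  expect_warning(p <- anchor_bin_profile(anchors, regions("chr1", 0, 100), 100),
                 "skipped 1")
  expect_equal(p$n_anchors, 1)
})

test_that("DEG linkage requires a new loop with a B2 anchor and a DEG promoter", {
  genes <- sort_regions(data.frame(chrom = "chr1", start = 95000, end = 120000,
                                   strand = "+", gene = "g1",
                                   stringsAsFactors = FALSE))
  degs <- data.frame(gene = "g1", log2fc = 1, p = 0.01)
  # loop anchor A covers the promoter (TSS 95000); anchor B carries the B2 peak
  lp <- loops("chr1", 94000, 98000, 300000, 304000, "KO")
  ctcf_up_b2 <- regions("chr1", 301000, 301400)
  lp$klass <- "new"
  out <- link_deg_loops(degs, genes, lp, ctcf_up_b2)
  expect_equal(out$gene, "g1")
  expect_equal(out$side, "left")
  lp$klass <- "unchanged"
  expect_equal(nrow(link_deg_loops(degs, genes, lp, ctcf_up_b2)), 0)
  # a DEG absent from the gene model is skipped with a warning
  degs2 <- rbind(degs, data.frame(gene = "ghost", log2fc = 1, p = 0.001))
  lp$klass <- "new"
  expect_warning(out2 <- link_deg_loops(degs2, genes, lp, ctcf_up_b2), "absent")
  expect_equal(out2$gene, "g1")
})
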