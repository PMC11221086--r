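# Fisher/BH statistics and TE / genomic-annotation enrichment tables.

test_that("fisher_test handles proportional and hand-enumerated tables", {
  r <- fisher_test(5, 5, 5, 5)
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p, 1)
  # support {0,1,2}: P(X=0)=P(X=2)=1/6, P(X=1)=4/6; two-sided p = 2/6
  expect_equal(fisher_test(2, 0, 0, 2)$p, 1 / 3, tolerance = 1e-12)
  expect_equal(fisher_test(2, 0, 0, 2)$odds_ratio, Inf)
  expect_equal(fisher_test(0, 2, 2, 0)$odds_ratio, 0)
  expect_error(fisher_test(0, 0, 0, 0), "zero")
  expect_error(fisher_test(1, -1, 0, 2), "non-negative")
})

test_that("fisher_test is invariant to transposing the table", {
  set.seed(9)
  for (rep in 1:25) {
    cells <- sample(0:12, 4, replace = TRUE)
    if (sum(cells) == 0) next
    p1 <- fisher_test(cells[1], cells[2], cells[3], cells[4])$p
    p2 <- fisher_test(cells[1], cells[3], cells[2], cells[4])$p
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("bh_adjust reproduces hand-computed step-up values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  # hand step-up: sorted (.005,.04,.2): adj = min over j>=i of p_j*m/j
  expect_equal(bh_adjust(c(0.2, 0.005, 0.04)), c(0.2, 0.015, 0.06))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

make_te_fixture <- function() {
  # 6 elements: 3 B2 subtypes + one B1 + one LINE
  sort_regions(data.frame(
    chrom = "chr1",
    start = c(1000, 3000, 5000, 7000, 9000, 12000),
    end = c(1200, 3200, 5200, 7200, 9200, 13000),
    strand = ".",
    te_class = c("SINE", "SINE", "SINE", "SINE", "SINE", "LINE"),
    te_family = c("B2", "B2", "B2", "B2", "B1", "L1"),
    te_subtype = c("B3", "B3", "B3A", "B2_Mm2", "B1_Mm", "L1Md"),
    stringsAsFactors = FALSE))
}

test_that("enrich_te with foreground = background gives FE 1 and p 1", {
  te <- make_te_fixture()
  peaks <- regions("chr1", c(950, 2950, 8950, 20000), c(1250, 3250, 9250, 20500))
  for (mode in c("count", "length")) {
    e <- enrich_te(peaks, peaks, te, level = "te_class", mode = mode)
    expect_true(all(abs(e$fold_enrichment[!is.na(e$fold_enrichment)] - 1) < 1e-12))
    expect_true(all(e$p[e$observed_in > 0] == 1))
  }
})

test_that("enrich_te count cells match manual counting and dedup per region", {
  te <- make_te_fixture()
  # peak A covers both B3 elements' windows? no: covers element 1 only;
  # peak B covers elements 2 (B3) and 3 (B3A); peak C off-TE
  peaks <- sort_regions(regions("chr1", c(900, 2900, 40000), c(1300, 5300, 40500)))
  fg <- peaks[1:2, ]
  e <- enrich_te(fg, peaks, te, overlap_rule(0.5, 0.5, TRUE), "b2_subtype", "count")
  b3 <- e[e$category == "B3", ]
  expect_equal(b3$observed_in, 2)     # both fg peaks hit a B3 element
  expect_equal(b3$observed_out, 0)
  expect_equal(b3$background_in, 2)
  expect_equal(b3$background_out, 1)
  b3a <- e[e$category == "B3A", ]
  expect_equal(b3a$observed_in, 1)    # only peak B reaches the B3A element
})

test_that("length mode equals count-on-elements when all lengths are equal", {
  te <- make_te_fixture()[1:5, ]       # all SINE elements are 200 bp
  peaks <- sort_regions(regions("chr1", c(900, 4900, 8900, 30000),
                                c(1300, 5300, 9300, 30400)))
  fg <- peaks[1:2, ]
  len <- enrich_te(fg, peaks, te, level = "sine_family", mode = "length")
  # every element is 200 bp, so the length cells must equal 200 x the
  # distinct-element counts computed independently with the pair oracle
  hit_el <- function(set) unique(oracle_intersect(set, te, 0.5, 0.5, TRUE)$target_i)
  fg_el <- hit_el(fg); bg_el <- hit_el(peaks)
  fam <- te$te_family
  b2 <- len[len$category == "B2", ]
  expect_equal(
    c(b2$observed_in, b2$observed_out, b2$background_in, b2$background_out),
    200 * c(sum(fam[fg_el] == "B2"), sum(fam[fg_el] != "B2"),
            sum(fam[bg_el] == "B2"), sum(fam[bg_el] != "B2")))
})

test_that("foreground must be a coordinate-subset of the background", {
  te <- make_te_fixture()
  bg <- regions("chr1", 1000, 2000)
  fg <- regions("chr1", 5000, 6000)
  expect_error(enrich_te(fg, bg, te), "subset")
})

test_that("adding category-hitting foreground regions cannot lower fold enrichment", {
  te <- make_te_fixture()
  peaks <- sort_regions(regions("chr1", c(900, 2900, 4900, 30000, 31000),
                                c(1300, 3300, 5300, 30400, 31400)))
  fg1 <- peaks[1, , drop = FALSE]
  fg2 <- peaks[1:2, ]                  # adds another B3-hitting region
  e1 <- enrich_te(fg1, peaks, te, level = "b2_subtype", mode = "count")
  e2 <- enrich_te(fg2, peaks, te, level = "b2_subtype", mode = "count")
  expect_gte(e2$fold_enrichment[e2$category == "B3"],
             e1$fold_enrichment[e1$category == "B3"])
})

test_that("annotate_regions is strand-aware with promoter precedence", {
  genes <- sort_regions(data.frame(
    chrom = "chr1", start = c(10000, 10000), end = c(20000, 20000),
    strand = c("+", "-"), gene = c("gp", "gm"), stringsAsFactors = FALSE))
  gp <- genes[genes$strand == "+", ]
  expect_equal(annotate_regions(regions("chr1", 7500, 8000), gp), "promoter")
  expect_equal(annotate_regions(regions("chr1", 15000, 15500), gp), "gene_body")
  expect_equal(annotate_regions(regions("chr1", 50000, 50100), gp), "intergenic")
  gm <- genes[genes$strand == "-", ]   # promoter window centred at 20000
  expect_equal(annotate_regions(regions("chr1", 22500, 22900), gm), "promoter")
  expect_equal(annotate_regions(regions("chr1", 15000, 15500), gm), "gene_body")
  no_strand <- gp; no_strand$strand <- "."
  expect_error(annotate_regions(regions("chr1", 0, 10), no_strand), "strand")
})

test_that("enrich_annotation recovers a promoter-rate ratio of 2", {
  genes <- sort_regions(data.frame(chrom = "chr1", start = 50000, end = 80000,
                                   strand = "+", gene = "g1",
                                   stringsAsFactors = FALSE))
  # background: 1 promoter region + 1 intergenic region (50% promoter)
  bg <- sort_regions(regions("chr1", c(48000, 200000), c(49000, 201000)))
  fg <- bg[1, , drop = FALSE]
  e <- enrich_annotation(fg, bg, genes)
  expect_equal(e$fold_enrichment[e$category == "promoter"], 2)
  expect_error(enrich_annotation(fg, bg[0, ], genes), "empty")
})
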