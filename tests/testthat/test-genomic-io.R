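# Readers/writers: coordinate conventions, direction thresholds,
# canonicalization, and round-trip fidelity.

test_that("BED parsing maps fields and skips track/comment lines", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=test", "# a comment",
               "chr1\t0\t100\tpk1\t0\t+",
               "chr1\t500\t680\tpk2\t3.5\t-",
               "chr2\t10\t20"), f)
  x <- read_regions(f, "bed")
  expect_equal(nrow(x), 3)
  expect_equal(x$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(x$start, c(0, 500, 10))
  expect_equal(x$end, c(100, 680, 20))
  expect_equal(x$strand, c("+", "-", "."))
  expect_equal(x$name[1], "pk1")
  expect_equal(x$score[2], 3.5)
})

test_that("invalid coordinates raise a parse error naming the offender", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100", "chr1\t250\t200"), f)
  expect_error(read_regions(f, "bed"), "start >= end")
})

test_that("diff_table assigns direction by the FDR and fold-change thresholds", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#chrom\tstart\tend\tlog2fc\tfdr",
               "chr1\t0\t100\t1.0\t0.01",    # up
               "chr1\t200\t300\t0.5\t0.01",  # ns: 0.5 < 0.585
               "chr1\t400\t500\t0.585\t0.049", # up: boundary inclusive
               "chr1\t600\t700\t-0.6\t0.01", # down
               "chr1\t800\t900\t1.0\t0.05"), f)  # ns: fdr not < 0.05
  x <- read_regions(f, "diff_table")
  expect_equal(x$direction, c("up", "ns", "up", "down", "ns"))
})

test_that("diff_table with a missing mandatory column raises a schema error", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#chrom\tstart\tend\tlog2fc", "chr1\t0\t100\t1.0"), f)
  expect_error(read_regions(f, "diff_table"), "missing column")
})

test_that("region tables round-trip through write/read", {
  x <- regions(c("chr1", "chr1", "chr2"), c(0, 500, 10), c(100, 680, 20),
               strand = c("+", "-", "."), name = c("a", "b", "c"),
               score = c(1, 2.5, 0))
  f <- withr::local_tempfile(fileext = ".bed")
  write_regions(x, f)
  y <- read_regions(f, "bed")
  expect_equal(y[, c("chrom", "start", "end", "strand", "name", "score")],
               x[, c("chrom", "start", "end", "strand", "name", "score")])
})

test_that("te_bed rows map to the TE hierarchy with element lengths", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("#chrom\tstart\tend\tte_class\tte_family\tte_subtype",
               "chr1\t500\t680\tSINE\tB2\tB3A"), f)
  x <- read_te_annotation(f, "te_bed")
  expect_equal(x$te_class, "SINE")
  expect_equal(x$te_family, "B2")
  expect_equal(x$te_subtype, "B3A")
  expect_equal(region_width(x), 180)
})

test_that("RepeatMasker rows convert 1-based begin and split class/family", {
  f <- withr::local_tempfile(fileext = ".out")
  writeLines(c(
    "   SW   perc perc perc  query     position in query    matching repeat",
    "score   div. del. ins.  sequence  begin end (left)     repeat class/family begin end (left) ID",
    "",
    " 1500   10.0  0.1  0.2  chr1      501   680  (1000)  + B3      SINE/B2     1 180 (0) 1",
    "  900   12.0  0.0  0.0  chr2      101   400  (2000)  C L1Md    LINE/L1     1 300 (0) 2"), f)
  x <- read_te_annotation(f, "repeatmasker_out")
  expect_equal(x$start, c(500, 100))
  expect_equal(x$end, c(680, 400))
  expect_equal(x$te_class, c("SINE", "LINE"))
  expect_equal(x$te_family, c("B2", "L1"))
  expect_equal(x$te_subtype, c("B3", "L1Md"))
  expect_equal(x$strand, c("+", "-"))
})

test_that("unsplittable class/family falls back to family = class with a warning", {
  f <- withr::local_tempfile(fileext = ".out")
  writeLines(" 100 1.0 0.0 0.0 chr1 11 60 (10) + AT_rich Low_complexity 1 50 (0) 1", f)
  expect_warning(x <- read_te_annotation(f, "repeatmasker_out"), "unsplittable")
  expect_equal(x$te_class, "Low_complexity")
  expect_equal(x$te_family, "Low_complexity")
})

test_that("BEDPE loops canonicalize anchors and skip inter-chromosomal rows", {
  f <- withr::local_tempfile(fileext = ".bedpe")
  writeLines(c("chr1\t50000\t60000\tchr1\t10000\t20000\tKO",  # swapped on read
               "chr1\t1000\t2000\tchr2\t5000\t6000\tKO",      # inter-chromosomal
               "chr1\t100000\t110000\tchr1\t300000\t310000\tKO"), f)
  expect_warning(x <- read_loops(f), "inter-chromosomal")
  expect_equal(nrow(x), 2)
  expect_true(all(x$start1 < x$start2))
  expect_equal(x$start1[1], 10000)
  expect_equal(x$genotype, c("KO", "KO"))
})

test_that("loops round-trip through BEDPE", {
  x <- loops("chr1", c(1000, 5000), c(2000, 6000), c(90000, 405000),
             c(91000, 406000), "WT")
  f <- withr::local_tempfile(fileext = ".bedpe")
  write_loops(x, f)
  expect_equal(read_loops(f), x)
})

test_that("CpG tables validate counts, groups and duplicates", {
  groups <- c(w1 = "WT", w2 = "WT", k1 = "KO", k2 = "KO")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#chrom\tpos\tw1.meth\tw1.total\tw2.meth\tw2.total\tk1.meth\tk1.total\tk2.meth\tk2.total",
               "chr1\t100\t3\t4\t0\t0\t1\t2\t0\t1",
               "chr1\t200\t2\t2\t1\t1\t0\t2\t2\t2"), f)
  x <- read_cpg_table(f, groups)
  expect_s3_class(x, "cpg_table")
  expect_equal(unname(x$meth[1, "w1"] / x$total[1, "w1"]), 0.75)
  # methylated > total
  writeLines(c("#chrom\tpos\tw1.meth\tw1.total\tk1.meth\tk1.total",
               "chr1\t100\t5\t4\t1\t2"), f)
  expect_error(read_cpg_table(f, groups), "methylated > total")
  # duplicate position
  writeLines(c("#chrom\tpos\tw1.meth\tw1.total\tk1.meth\tk1.total",
               "chr1\t100\t1\t4\t1\t2", "chr1\t100\t2\t4\t1\t2"), f)
  expect_error(read_cpg_table(f, groups), "duplicate")
  # sample without a group assignment
  writeLines(c("#chrom\tpos\tzz.meth\tzz.total\tk1.meth\tk1.total",
               "chr1\t100\t1\t4\t1\t2"), f)
  expect_error(read_cpg_table(f, groups), "without group")
  # empty table warns
  writeLines("#chrom\tpos\tw1.meth\tw1.total\tk1.meth\tk1.total", f)
  expect_warning(x0 <- read_cpg_table(f, groups), "empty")
  expect_equal(length(x0$pos), 0)
})

test_that("cpg tables round-trip through write/read", {
  groups <- c(w1 = "WT", k1 = "KO")
  x <- cpg_table(c("chr1", "chr1", "chr2"), c(10, 400, 7),
                 matrix(c(1L, 2L, 0L, 3L, 1L, 2L), ncol = 2,
                        dimnames = list(NULL, c("w1", "k1"))),
                 matrix(c(4L, 2L, 1L, 3L, 2L, 5L), ncol = 2,
                        dimnames = list(NULL, c("w1", "k1"))), groups)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cpg_table(x, f)
  y <- read_cpg_table(f, groups)
  expect_equal(y$chrom, x$chrom)
  expect_equal(y$pos, x$pos)
  expect_equal(y$meth, x$meth)
  expect_equal(y$total, x$total)
})

test_that("readers emit (chrom, start)-sorted output", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr2\t10\t20", "chr1\t500\t680", "chr1\t0\t100"), f)
  x <- read_regions(f, "bed")
  expect_true(is_sorted_regions(x))
})
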