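test_that("read_fragments parses 10x-style records", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment line", "chr1\t10\t110\tAAAC\t3",
               "chr1\t20\t120\tTTTG\t1"), f)
  fr <- read_fragments(f)
  expect_equal(nrow(fr), 2)
  expect_equal(as.list(fr[1]), list(chrom = "chr1", start = 10L, end = 110L,
                                    barcode = "AAAC", dup_count = 3L))
  # whitelist filtering
  expect_equal(read_fragments(f, barcode_whitelist = "AAAC")$barcode, "AAAC")
})

test_that("read_fragments defaults dup_count, handles gzip, flags bad lines", {
  f4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chr1\t10\t110\tAAAC", f4)
  expect_equal(read_fragments(f4)$dup_count, 1L)

  gz <- withr::local_tempfile(fileext = ".tsv.gz")
  con <- gzfile(gz, "w"); writeLines("chr2\t5\t105\tCCCC\t2", con); close(con)
  expect_equal(read_fragments(gz)$chrom, "chr2")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chr1\t10\t110\tAAAC", "chr1\tx\t5\tAAAC"), bad)
  expect_error(read_fragments(bad), "line 2")
})

test_that("count_fragments assigns fragments to their midpoint bin", {
  b <- tiny_bins(3, w = 100)
  fr <- data.frame(chrom = "chr1", start = 50, end = 150, barcode = "A",
                   dup_count = 1)
  m <- count_fragments(fr, b)
  expect_equal(unname(m$counts["A", ]), c(0, 1, 0))  # midpoint 100

  fr2 <- rbind(fr, fr)
  expect_equal(max(count_fragments(fr2, b)$counts), 2)

  fr3 <- rbind(fr, data.frame(chrom = "chrZ", start = 0, end = 10,
                              barcode = "A", dup_count = 1))
  expect_message(m3 <- count_fragments(fr3, b), "1 fragment")
  expect_equal(attr(m3, "n_unassigned"), 1)
  # conservation: assigned fragments equal the matrix total
  expect_equal(sum(m3$counts), nrow(fr3) - 1)
})

test_that("filter_cells keeps cells at or above the threshold", {
  m <- tiny_cm(matrix(c(100, 5000, 20000), nrow = 3, ncol = 1))
  expect_equal(nrow(filter_cells(m, 20000)$counts), 1)
  expect_equal(filter_cells(m, 0)$cell_ids, m$cell_ids)
  meq <- tiny_cm(matrix(7, nrow = 3, ncol = 1))
  expect_equal(nrow(filter_cells(meq, 7)$counts), 3)
  expect_error(filter_cells(m, 1e9), "threshold")
})

test_that("filter_zero_bins drops bins zero in strictly more than zero_frac", {
  v <- matrix(1, nrow = 100, ncol = 3)
  v[1:86, 1] <- 0   # 0.86 > 0.85 -> removed
  v[1:85, 2] <- 0   # 0.85 -> kept
  m <- filter_zero_bins(tiny_cm(v))
  expect_equal(ncol(m$counts), 2)
  expect_equal(nrow(m$bins), 2)
  expect_equal(m$bins$index, 0:1)
  expect_error(filter_zero_bins(tiny_cm(matrix(0, 2, 2))), "all bins")
})

test_that("gc_correct is a near-identity when counts are GC-independent", {
  set.seed(11)
  gc <- runif(600, 0.3, 0.6)
  x <- rpois(600, 50)
  m <- tiny_cm(x, gc = gc)
  corr <- gc_correct(m)
  expect_true(corr$corrected)
  expect_lt(max(abs(corr$counts - m$counts)) / mean(x), 0.15)
  expect_lt(abs(mean(corr$counts) - mean(x)) / mean(x), 0.05)
})

test_that("gc_correct removes a pure linear GC trend", {
  set.seed(12)
  gc <- runif(1000, 0.3, 0.6)
  x <- rpois(1000, 50 * gc)
  m <- tiny_cm(x, gc = gc)
  expect_gt(cor(x, gc), 0.5)
  corr <- gc_correct(m)
  expect_lt(abs(cor(corr$counts[1, ], gc)), 0.1)
  # correction is mean-preserving within 5%
  expect_lt(abs(mean(corr$counts) - mean(x)) / mean(x), 0.05)
})

test_that("gc_correct skips cells with too few distinct GC values", {
  m <- tiny_cm(matrix(5, 1, 20), gc = rep(c(0.4, 0.5), 10))
  expect_warning(corr <- gc_correct(m), "distinct GC")
  expect_equal(unname(corr$counts), unname(m$counts))
})

test_that("count matrices export to MTX with label sidecars", {
  m <- tiny_cm(rbind(c(0, 2, 1), c(3, 0, 0)))
  prefix <- file.path(withr::local_tempdir(), "cm")
  export_counts(m, prefix)
  mm <- Matrix::readMM(paste0(prefix, ".mtx"))
  expect_equal(unname(as.matrix(Matrix::t(mm))), unname(m$counts))
  expect_equal(readLines(paste0(prefix, ".cells.tsv")), m$cell_ids)
})
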