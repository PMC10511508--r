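test_that("ad_distance matches its frozen tied-sample values", {
  expect_identical(ad_distance(c(5, 5), c(5, 5)), 0)
  # binding value under the discrete tie-aware form; the classical
  # continuous form on the same (tied) input would give 5/3
  expect_equal(ad_distance(c(0, 0), c(10, 10)), 2)
  expect_equal(ad_oracle(c(0, 0), c(10, 10)), 2)
  expect_identical(ad_distance(c(3, 7, 2), c(2, 3, 7)), 0)
  expect_error(ad_distance(numeric(0), 1), "non-empty")
})

test_that("ad_distance equals brute-force evaluation of the discrete sum", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(1:19, 1)
    m <- sample(1:19, 1)
    left <- rpois(n, sample(c(2, 8, 30), 1))
    right <- rpois(m, sample(c(2, 8, 30), 1))
    expect_lt(abs(ad_distance(left, right) - ad_oracle(left, right)), 1e-10)
  }
})

test_that("the tie-aware form agrees with the continuous form on distinct data", {
  set.seed(102)
  for (i in 1:20) {
    v <- sample(1:10000, 15)
    left <- v[1:7]; right <- v[8:15]
    expect_equal(ad_distance(left, right), ad_continuous_oracle(left, right),
                 tolerance = 1e-12)
  }
})

test_that("ad_distance is permutation- and shift-invariant, and zero iff equal", {
  set.seed(103)
  for (i in 1:50) {
    left <- rpois(sample(2:12, 1), 10)
    right <- rpois(sample(2:12, 1), 15)
    a0 <- ad_distance(left, right)
    expect_equal(ad_distance(sample(left), sample(right)), a0)
    expect_equal(ad_distance(left + 7, right + 7), a0)
    expect_identical(ad_distance(left, sample(left)), 0)
    if (!setequal(left, right) ||
        !identical(sort(left), sort(right))) expect_gt(a0, 0)
  }
})

test_that("best_split finds the step and respects min_size", {
  sp <- best_split(c(rep(10, 5), rep(2, 5)))
  expect_equal(sp$split_index, 5)
  # brute-force agreement on random vectors
  set.seed(104)
  for (i in 1:20) {
    x <- rpois(sample(6:20, 1), 8)
    expect_equal(best_split(x)$split_index, best_split_oracle(x)$split_index)
  }
  # constant vector still returns a (weak) split; pruning handles it later
  expect_false(is.null(best_split(rep(4, 10))))
  expect_null(best_split(5, min_size = 1))
  expect_null(best_split(rpois(5, 4), min_size = 3))
})

test_that("segment_chromosome recovers clean Poisson steps", {
  hits <- 0
  for (s in 1:40) {
    set.seed(s)
    x <- c(rpois(50, 10), rpois(50, 20), rpois(50, 10))
    bp <- segment_chromosome(x, k_max = 2)
    hits <- hits + (nrow(bp) == 2 &&
                    all(abs(sort(bp$split_index) - c(50, 100)) <= 2))
  }
  expect_gte(hits / 40, 0.95)
})

test_that("segment_chromosome respects k_max and minimum sizes", {
  x <- rpois(40, 10)
  expect_equal(nrow(segment_chromosome(x, k_max = 0)), 0)
  expect_equal(nrow(segment_chromosome(rpois(3, 10), min_size = 2)), 0)
  bp <- segment_chromosome(c(rpois(50, 5), rpois(50, 25)), k_max = 15)
  expect_lte(nrow(bp), 15)
  expect_equal(bp$split_index, sort(bp$split_index))
  expect_true(all(bp$ad >= 0))
})

test_that("prune_breakpoints drops strictly below the per-cell mean AD", {
  bp <- data.frame(cell = "c1", chrom = "chr1", split_index = c(5L, 9L, 14L),
                   ad = c(10, 2, 6), depth = 1:3, kept = NA)
  pr <- prune_breakpoints(bp)
  expect_equal(pr$kept, c(TRUE, FALSE, TRUE))   # mean 6; boundary kept
  expect_equal(unname(attr(pr, "prune_threshold")["c1"]), 6)

  same <- prune_breakpoints(transform(bp, ad = 4))
  expect_true(all(same$kept))

  single <- prune_breakpoints(bp[1, ])
  expect_true(single$kept)

  # thresholds are per cell, not pooled
  two <- prune_breakpoints(rbind(bp, transform(bp, cell = "c2", ad = c(100, 40, 70))))
  expect_equal(two$kept, rep(c(TRUE, FALSE, TRUE), 2))
})

test_that("breakpoint tables export with genome coordinates", {
  m <- tiny_cm(rbind(c(rep(20, 5), rep(5, 5))), w = 1000)
  bp <- prune_breakpoints(segment_cells(m, k_max = 1))
  expect_equal(bp$split_index, 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_breakpoints(bp, m$bins, path)
  out <- read.delim(path)
  expect_equal(out$coord, 5000)
  expect_true(out$kept)
})
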