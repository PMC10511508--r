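test_that("pseudobulk averages copy states on the 1/2/3 scale", {
  k <- rbind(c(1L, 2L, 1L), c(1L, 0L, 2L))
  expect_equal(pseudobulk(k), c(2, 2, 2.5))   # gain+loss average to 2
  expect_equal(pseudobulk(rbind(rep(2L, 4))), rep(3, 4))
  expect_equal(pseudobulk(rbind(rep(1L, 4), rep(1L, 4))), rep(2, 4))
  expect_error(pseudobulk(matrix(integer(), 0, 3)), "no cells")
})

test_that("standardize_profile centers and scales by the population sd", {
  expect_equal(standardize_profile(c(1, 2, 3)), c(-1.2247, 0, 1.2247),
               tolerance = 1e-4)
  z <- standardize_profile(rnorm(50))
  expect_equal(standardize_profile(z), z)
  expect_error(standardize_profile(rep(2, 5)), "constant")
})

test_that("profile_mse supports both normalizations", {
  expect_equal(profile_mse(1:4, 1:4), 0)
  expect_equal(profile_mse(2:5, 1:4), 1)
  expect_equal(profile_mse(2:5, 1:4, per_bin_squared = TRUE), 0.25)
  expect_equal(profile_mse(3, 0), 9)
  expect_error(profile_mse(1:3, 1:4), "mismatch")
})

test_that("classify_profile thresholds with boundary-normal semantics", {
  expect_equal(classify_profile(c(1.2, 2.0, 2.9), 1.8, 2.2), c(0L, 1L, 2L))
  expect_equal(classify_profile(c(1.99, 2, 2.01), 2, 2), c(0L, 1L, 2L))
  expect_equal(classify_profile(c(1.9, 2.1), 1.8, 2.2), c(1L, 1L))
  expect_error(classify_profile(1:3, 2.2, 1.8), "c_low <= c_high")
})

test_that("prf1 reproduces the tp/fp/fn arithmetic per state", {
  pred <- c(rep(2L, 10), rep(1L, 10))
  truth <- c(rep(2L, 8), 1L, 1L, rep(1L, 8), 2L, 2L)
  pr <- prf1(pred, truth)
  g <- pr[pr$state == "gain", ]
  expect_equal(c(g$tp, g$fp, g$fn), c(8, 2, 2))
  expect_equal(c(g$precision, g$recall, g$f1), c(0.8, 0.8, 0.8))

  perfect <- prf1(truth, truth)
  expect_true(all(perfect$f1[perfect$defined] == 1))

  # absent state flagged undefined, reported as 0
  none <- prf1(rep(1L, 5), rep(1L, 5))
  expect_false(none$defined[none$state == "loss"])
  expect_equal(none$f1[none$state == "loss"], 0)

  # micro-count identity: sum of tp over states = agreeing positions
  set.seed(41)
  a <- sample(0:2, 200, TRUE); b <- sample(0:2, 200, TRUE)
  expect_equal(sum(prf1(a, b)$tp), sum(a == b))
  expect_error(prf1(1:3, 1:4), "mismatch")
})

test_that("concordance_vs_reference restricts to common cells and bins", {
  k <- rbind(c(1L, 1L, 0L, 2L), c(1L, 1L, 1L, 1L))
  dimnames(k) <- list(c("a", "b"), paste0("bin", 1:4))
  expect_equal(concordance_vs_reference(k, k)$overall, 1)
  expect_equal(unname(concordance_vs_reference(k, k)$per_state),
               c(1, 1, 1))

  k2 <- k; k2["a", 1] <- 0L
  cc <- concordance_vs_reference(k2, k)
  expect_equal(unname(cc$per_state["normal"]), 5 / 6)
  expect_equal(cc$overall, 7 / 8)

  # extra cells in one matrix are excluded from the denominator
  k3 <- rbind(k, c(0L, 0L, 0L, 0L))
  rownames(k3) <- c("a", "b", "zz")
  expect_equal(concordance_vs_reference(k3, k)$overall, 1)
  kx <- k; rownames(kx) <- c("q", "r")
  expect_error(concordance_vs_reference(kx, k), "common")
})

test_that("scan_thresholds finds the per-state optimum on a clean profile", {
  truth <- c(rep(0L, 5), rep(1L, 10), rep(2L, 5))
  profile <- c(rep(1.5, 5), rep(2, 10), rep(2.5, 5))
  expect_equal(unname(scan_thresholds(profile, truth)), c(1, 1, 1))
})

test_that("metrics reports write JSON plus TSV tables", {
  dir <- withr::local_tempdir()
  pr <- prf1(c(0L, 1L, 2L), c(0L, 1L, 1L))
  write_metrics(list(prf1 = pr, mse = 0.25), file.path(dir, "m"))
  j <- jsonlite::read_json(file.path(dir, "m.json"))
  expect_equal(j$mse, 0.25)
  expect_true(file.exists(file.path(dir, "m.prf1.tsv")))
})
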