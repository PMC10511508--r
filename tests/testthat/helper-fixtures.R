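# Small in-code fixtures shared across test files.

# a bin_set of `n` bins of width `w` on one chromosome, optional gc
tiny_bins <- function(n = 5, w = 100L, chrom = "chr1", gc = NULL) {
  b <- make_bins(stats::setNames(n * w, chrom), w)
  if (!is.null(gc)) b$gc <- gc
  b
}

# count_matrix straight from a plain matrix
tiny_cm <- function(values, w = 100L, gc = NULL, corrected = FALSE) {
  values <- rbind(values)
  b <- tiny_bins(ncol(values), w = w, gc = gc)
  count_matrix(values, sprintf("c%02d", seq_len(nrow(values))), b,
               corrected = corrected)
}

# the frozen benchmark configuration used by the end-to-end checks
ref_fit <- function(seed = 1L, n_cells = 200L) {
  rs <- reference_sim(seed = seed, n_cells = n_cells)
  sim <- simulate_counts(rs$cfg, rs$clones)
  list(sim = sim, fit = call_cna(sim$counts))
}
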