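# Concordance machinery: pseudo-bulk profiles, MSE, threshold
# classification, per-state precision/recall/F1, and state retention for
# downsampling studies.

STATE_NAMES <- c("loss", "normal", "gain")

#' Pseudo-bulk copy-number profile
#'
#' Per-bin mean copy number across cells on the 1/2/3 scale: each loss
#' contributes 1, each normal 2 and each gain 3, averaged over cells, so an
#' all-normal bin scores exactly 2.
#'
#' @param k karyotype matrix (cells x bins, values 0/1/2).
#' @return numeric vector of per-bin values in [1, 3].
#' @export
pseudobulk <- function(k) {
  if (is.null(dim(k)) || nrow(k) == 0) stop("no cells")
  colMeans(k + 1)
}

#' Standardize a profile to mean 0 and unit standard deviation
#'
#' Used to place copy-number profiles from different modalities on the same
#' scale before correlation or MSE comparisons.
#'
#' @param profile non-constant numeric vector.
#' @details The population (1/N) standard deviation is used, so a
#'   standardized vector is a fixed point of the transformation.
#' @export
standardize_profile <- function(profile) {
  ctr <- profile - mean(profile)
  s <- sqrt(mean(ctr^2))
  if (is.na(s) || s == 0) stop("constant profile cannot be standardized")
  ctr / s
}

#' Mean squared error between two profiles
#'
#' The default is the conventional mean over bins, `sum((a-b)^2) / N`. With
#' `per_bin_squared = TRUE` the sum is divided by N^2 instead, an alternative
#' normalization some reports use; both are provided for literal
#' reproduction.
#'
#' @param a,b equal-length numeric vectors.
#' @param per_bin_squared divide by N^2 instead of N.
#' @export
profile_mse <- function(a, b, per_bin_squared = FALSE) {
  if (length(a) != length(b)) stop("length mismatch")
  s <- sum((a - b)^2)
  if (per_bin_squared) s / length(a)^2 else s / length(a)
}

#' Classify a pseudo-bulk profile into loss/normal/gain
#'
#' Bins above `c_high` are called gain, below `c_low` loss, and the rest
#' normal (boundary values are normal).
#'
#' @param profile numeric vector (typically mean copy number on the 1/2/3
#'   scale).
#' @param c_low,c_high thresholds with `c_low <= c_high`.
#' @return integer state vector (0 loss, 1 normal, 2 gain).
#' @export
classify_profile <- function(profile, c_low, c_high) {
  stopifnot(c_low <= c_high)
  ifelse(profile > c_high, 2L, ifelse(profile < c_low, 0L, 1L))
}

#' Per-state precision, recall and F1
#'
#' For each state s, tp = bins with state s in both prediction and truth,
#' fp = predicted s but truth differs, fn = truth s but prediction differs;
#' precision = tp/(tp+fp), recall = tp/(tp+fn), F1 = 2PR/(P+R). Undefined
#' (0/0) ratios are reported as 0 and flagged.
#'
#' @param pred,truth equal-length state vectors (0/1/2).
#' @return data.frame with one row per state: tp, fp, fn, precision, recall,
#'   f1 and a `defined` flag.
#' @export
prf1 <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  out <- lapply(0:2, function(s) {
    tp <- sum(pred == s & truth == s)
    fp <- sum(pred == s & truth != s)
    fn <- sum(pred != s & truth == s)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
    data.frame(state = STATE_NAMES[s + 1], tp = tp, fp = fp, fn = fn,
               precision = p, recall = r, f1 = f1,
               defined = (tp + fp > 0) && (tp + fn > 0))
  })
  do.call(rbind, out)
}

#' State retention between two karyotype matrices
#'
#' For downsampling/robustness studies: restricted to the cells and bins
#' present in both matrices, computes the overall fraction of entries whose
#' state is unchanged, and per reference state the fraction retained (the
#' complement of the lost-state fraction).
#'
#' @param k_test karyotype matrix under test (e.g. from downsampled data).
#' @param k_ref reference karyotype matrix (e.g. the fully covered run).
#' @return list(overall, per_state) where `per_state` is a named vector over
#'   loss/normal/gain (NA for states absent from the reference).
#' @export
concordance_vs_reference <- function(k_test, k_ref) {
  cells <- intersect(rownames(k_test), rownames(k_ref))
  bins <- intersect(colnames(k_test), colnames(k_ref))
  if (length(cells) == 0 || length(bins) == 0)
    stop("no common cells/bins between the two matrices")
  a <- k_test[cells, bins, drop = FALSE]
  b <- k_ref[cells, bins, drop = FALSE]
  per_state <- vapply(0:2, function(s) {
    n <- sum(b == s)
    if (n == 0) NA_real_ else sum(a == s & b == s) / n
  }, numeric(1))
  names(per_state) <- STATE_NAMES
  list(overall = mean(a == b), per_state = per_state)
}

#' Maximum per-state F1 over classification thresholds
#'
#' Scans a grid of (c_low, c_high) threshold pairs, classifies the predicted
#' pseudo-bulk profile at each pair and scores it against a fixed truth
#' classification, returning for each state the maximum F1 attained (the
#' same max-over-thresholds summary used when comparing copy-number
#' profiles across modalities).
#'
#' @param profile predicted pseudo-bulk profile (1-3 scale).
#' @param truth_states truth state vector (0/1/2).
#' @param c_lows,c_highs threshold grids.
#' @return named numeric vector (loss, normal, gain) of best F1 per state.
#' @export
scan_thresholds <- function(profile, truth_states,
                            c_lows = seq(1.5, 1.95, by = 0.05),
                            c_highs = seq(2.05, 2.5, by = 0.05)) {
  best <- c(loss = 0, normal = 0, gain = 0)
  for (cl in c_lows) for (ch in c_highs) {
    f <- prf1(classify_profile(profile, cl, ch), truth_states)$f1
    best <- pmax(best, f)
  }
  best
}

#' Write a metrics report as JSON and TSV
#'
#' @param metrics a named list of scalars and/or data.frames (e.g. output of
#'   [prf1()], [profile_mse()], [concordance_vs_reference()]).
#' @param prefix output path prefix; writes `<prefix>.json` and, for each
#'   data.frame element, `<prefix>.<name>.tsv`.
#' @export
write_metrics <- function(metrics, prefix) {
  jsonlite::write_json(metrics, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  for (nm in names(metrics))
    if (is.data.frame(metrics[[nm]]))
      data.table::fwrite(metrics[[nm]], paste0(prefix, ".", nm, ".tsv"),
                         sep = "\t")
  invisible(prefix)
}
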