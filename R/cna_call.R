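# The one-stop fitter: filtered counts -> segmentation -> pruning -> states.

#' Call copy-number alterations per cell
#'
#' Runs the full calling pipeline on a binned count matrix: optional cell
#' and zero-bin filtering, optional GC correction, per-cell per-chromosome
#' iterative binary segmentation scored by the Anderson-Darling distance,
#' pruning of breakpoints weaker than the cell's genome-wide mean distance,
#' and copy-state assignment from rounded trimmed-mean fold changes.
#'
#' @param m a `count_matrix` (raw or already GC-corrected).
#' @param k_max maximum breakpoints per chromosome (default 15).
#' @param min_size minimum bins on each side of a split (default 1).
#' @param trim trimmed-mean fraction for segment and genome means
#'   (default 0.1).
#' @param min_frags drop cells with fewer total fragments (default 0: the
#'   matrix is assumed pre-filtered; a typical value for real data is
#'   20,000).
#' @param zero_frac drop bins with zero counts in more than this fraction of
#'   cells (default 0.85); set to NULL to skip.
#' @param correct_gc GC-correct raw counts before segmenting (requires bin
#'   GC content; default TRUE when GC is available).
#' @param loess_span span of the GC LOESS fit.
#' @return an object of class `cna_call`: list with elements `karyotype`
#'   (cells x bins matrix of 0/1/2), `segments` (per-segment table with
#'   trimmed mean, z-score, fold change and state), `breakpoints` (with AD
#'   distances and kept flags), `counts` (the matrix that was segmented),
#'   `bins`, and `params`.
#' @seealso [simulate_counts()] to generate inputs, [cluster_karyotypes()]
#'   and [plot.cna_call()] for clone structure.
#' @export
call_cna <- function(m, k_max = 15L, min_size = 1L, trim = 0.1,
                     min_frags = 0, zero_frac = 0.85,
                     correct_gc = !anyNA(m$bins$gc), loess_span = 0.75) {
  stopifnot(inherits(m, "count_matrix"))
  if (!m$corrected) {
    if (min_frags > 0) m <- filter_cells(m, min_frags)
    if (!is.null(zero_frac)) m <- filter_zero_bins(m, zero_frac)
    if (correct_gc) m <- gc_correct(m, loess_span = loess_span)
  }
  bp <- prune_breakpoints(segment_cells(m, k_max = k_max,
                                        min_size = min_size))
  chroms <- unique(m$bins$chrom)
  offset <- c(0, cumsum(table(factor(m$bins$chrom, levels = chroms))))
  names(offset) <- c(chroms, "..end")
  seg_list <- list()
  for (ci in seq_along(m$cell_ids)) {
    cell <- m$cell_ids[ci]
    kept <- bp[bp$cell == cell & bp$kept %in% TRUE, , drop = FALSE]
    segs <- segments_from_breakpoints(m$bins, kept)
    tms <- vapply(seq_len(nrow(segs)), function(i) {
      cols <- offset[[segs$chrom[i]]] + seq.int(segs$start_bin[i] + 1L,
                                                segs$end_bin[i])
      trimmed_segment_mean(m$counts[ci, cols], trim)
    }, numeric(1))
    gm <- trimmed_segment_mean(m$counts[ci, ], trim)
    st <- assign_states(tms, gm)
    seg_list[[ci]] <- data.frame(cell = cell, segs, st,
                                 genome_mean = gm, row.names = NULL)
  }
  segments <- do.call(rbind, seg_list)
  fit <- structure(list(
    karyotype = karyotype_matrix(segments, m$bins),
    segments = segments,
    breakpoints = bp,
    counts = m,
    bins = m$bins,
    params = list(k_max = k_max, min_size = min_size, trim = trim,
                  zero_frac = zero_frac, loess_span = loess_span)),
    class = "cna_call")
  fit
}

#' @export
print.cna_call <- function(x, ...) {
  k <- x$karyotype
  cat(sprintf("cna_call: %d cells x %d bins\n", nrow(k), ncol(k)))
  frac <- table(factor(k, levels = 0:2)) / length(k)
  cat(sprintf("  bins called loss %.1f%%, normal %.1f%%, gain %.1f%%\n",
              100 * frac[1], 100 * frac[2], 100 * frac[3]))
  invisible(x)
}

#' @export
summary.cna_call <- function(object, ...) {
  k <- object$karyotype
  per_cell <- data.frame(
    cell = rownames(k),
    frac_loss = rowMeans(k == 0),
    frac_normal = rowMeans(k == 1),
    frac_gain = rowMeans(k == 2),
    n_breakpoints = as.integer(table(factor(
      object$breakpoints$cell[object$breakpoints$kept %in% TRUE],
      levels = rownames(k)))),
    row.names = NULL)
  out <- list(per_cell = per_cell,
              n_segments = nrow(object$segments),
              params = object$params)
  class(out) <- "summary.cna_call"
  out
}

#' @export
print.summary.cna_call <- function(x, ...) {
  cat(sprintf("cna_call with %d cells, %d segments\n",
              nrow(x$per_cell), x$n_segments))
  print(utils::head(x$per_cell, 10))
  invisible(x)
}

#' Plot a fitted cna_call as a karyogram heatmap
#'
#' @param x a `cna_call`.
#' @param path optional PNG path; see [plot_karyogram()].
#' @param clones optional clone assignment from [cluster_karyotypes()].
#' @param ... passed to [plot_karyogram()].
#' @export
plot.cna_call <- function(x, path = NULL, clones = NULL, ...) {
  plot_karyogram(x$karyotype, clones = clones, path = path, ...)
}

#' Write the per-segment table as TSV
#'
#' One row per segment: cell, chromosome, bin range, trimmed mean, z-score,
#' fold change and state.
#'
#' @param fit a `cna_call`.
#' @param path output path.
#' @export
write_segments <- function(fit, path) {
  data.table::fwrite(fit$segments, path, sep = "\t")
  invisible(path)
}
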