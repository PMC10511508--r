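# Fragment I/O, binned counting, cell/bin filtering and GC correction.

new_count_matrix <- function(values, cell_ids, bins, corrected = FALSE) {
  values <- as.matrix(values)
  dimnames(values) <- list(cell_ids, bin_labels(bins))
  structure(list(counts = values, cell_ids = cell_ids, bins = bins,
                 corrected = corrected),
            class = "count_matrix")
}

#' Construct a cells x bins count matrix
#'
#' Wraps a plain matrix of per-cell, per-bin fragment counts together with
#' its cell identifiers and the `bin_set` the columns refer to.
#'
#' @param values numeric matrix, one row per cell, one column per bin.
#' @param cell_ids character vector of cell barcodes (row labels).
#' @param bins a `bin_set` with as many bins as `values` has columns.
#' @param corrected whether values are GC-corrected (real) rather than raw
#'   integer counts.
#' @return a `count_matrix`.
#' @export
count_matrix <- function(values, cell_ids, bins, corrected = FALSE) {
  values <- as.matrix(values)
  stopifnot(inherits(bins, "bin_set"), ncol(values) == nrow(bins),
            nrow(values) == length(cell_ids), all(values >= 0))
  new_count_matrix(values, cell_ids, bins, corrected)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d cells x %d bins (%s)\n",
              nrow(x$counts), ncol(x$counts),
              if (x$corrected) "GC-corrected" else "raw"))
  invisible(x)
}

#' Read a 10x-style fragments file
#'
#' Tab-separated columns chrom, start, end, barcode and optionally a
#' duplicate count; gzipped files are handled transparently and lines
#' starting with '#' are skipped. Coordinates are 0-based half-open.
#'
#' @param path fragments.tsv or fragments.tsv.gz.
#' @param barcode_whitelist optional character vector; records with other
#'   barcodes are dropped.
#' @return data.table with columns chrom, start, end, barcode, dup_count
#'   (1 when the file has no count column), in file order.
#' @export
read_fragments <- function(path, barcode_whitelist = NULL) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  lines <- readLines(con)
  close(con)
  line_no <- seq_along(lines)
  keep <- !startsWith(lines, "#")
  lines <- lines[keep]; line_no <- line_no[keep]
  if (length(lines) == 0)
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), barcode = character(),
                                  dup_count = integer()))
  dt <- data.table::fread(text = lines, header = FALSE, sep = "\t",
                          fill = TRUE, colClasses = "character")
  if (ncol(dt) < 4) stop("fragments file needs >= 4 columns")
  start <- suppressWarnings(as.integer(dt[[2]]))
  end <- suppressWarnings(as.integer(dt[[3]]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("non-integer coordinates at line ", line_no[bad[1]])
  dup <- if (ncol(dt) >= 5) suppressWarnings(as.integer(dt[[5]])) else
    rep(1L, nrow(dt))
  dup[is.na(dup)] <- 1L
  out <- data.table::data.table(chrom = dt[[1]], start = start, end = end,
                                barcode = dt[[4]], dup_count = dup)
  if (!is.null(barcode_whitelist)) out <- out[out$barcode %in% barcode_whitelist]
  out[]
}

#' Count fragments per cell and bin
#'
#' Each fragment is assigned to the single bin containing its midpoint, so a
#' sequenced molecule is counted exactly once. Fragments whose midpoint falls
#' outside every retained bin (unbinned contigs, blacklisted gaps) are
#' ignored; their tally is stored in the `n_unassigned` attribute.
#'
#' @param fragments data.table from [read_fragments()] (or any table with
#'   chrom/start/end/barcode/dup_count).
#' @param bins a `bin_set`.
#' @param weight_duplicates if TRUE each record contributes `dup_count`
#'   instead of 1 (PCR-duplicate weighting; off by default).
#' @return a raw `count_matrix` (cells ordered by sorted barcode).
#' @export
count_fragments <- function(fragments, bins, weight_duplicates = FALSE) {
  stopifnot(inherits(bins, "bin_set"))
  fr <- data.table::copy(data.table::as.data.table(fragments))
  cells <- sort(unique(fr$barcode))
  mat <- matrix(0L, nrow = length(cells), ncol = nrow(bins))
  n_unassigned <- 0L
  if (nrow(fr) > 0) {
    fr[, mid := (start + end) %/% 2L]
    fr[, bin_row := NA_integer_]
    for (ch in unique(bins$chrom)) {
      bsel <- which(bins$chrom == ch)
      fsel <- which(fr$chrom == ch)
      if (!length(fsel)) next
      idx <- findInterval(fr$mid[fsel], bins$start[bsel])
      ok <- idx >= 1 & fr$mid[fsel] < bins$end[bsel][pmax(idx, 1L)]
      fr$bin_row[fsel[ok]] <- bsel[idx[ok]]
    }
    n_unassigned <- sum(is.na(fr$bin_row))
    hit <- fr[!is.na(fr$bin_row)]
    if (nrow(hit) > 0) {
      agg <- hit[, list(count = if (weight_duplicates) sum(dup_count) else .N),
                 by = list(barcode, bin_row)]
      mat[cbind(match(agg$barcode, cells), agg$bin_row)] <- agg$count
    }
  }
  if (n_unassigned > 0)
    message(n_unassigned, " fragment(s) outside retained bins ignored")
  cm <- new_count_matrix(mat, cells, bins, corrected = FALSE)
  attr(cm, "n_unassigned") <- n_unassigned
  cm
}

#' Filter lowly covered cells
#'
#' Cells with total fragment count below `min_frags` are removed (cells at
#' exactly the threshold are kept). Order of survivors is preserved.
#'
#' @param m a raw `count_matrix`.
#' @param min_frags minimum total count per cell (default 20,000).
#' @export
filter_cells <- function(m, min_frags = 20000) {
  stopifnot(inherits(m, "count_matrix"))
  keep <- rowSums(m$counts) >= min_frags
  if (!any(keep))
    stop("all cells removed by min_frags = ", min_frags,
         "; lower the threshold")
  new_count_matrix(m$counts[keep, , drop = FALSE], m$cell_ids[keep],
                   m$bins, m$corrected)
}

#' Remove bins that are zero in most cells
#'
#' A bin is removed iff the fraction of cells with zero count in it is
#' strictly greater than `zero_frac`; this discards regions of low
#' mappability specific to the dataset. Surviving bins are re-indexed.
#'
#' @param m a raw `count_matrix`.
#' @param zero_frac removal threshold (default 0.85).
#' @export
filter_zero_bins <- function(m, zero_frac = 0.85) {
  stopifnot(inherits(m, "count_matrix"), zero_frac > 0, zero_frac <= 1)
  frac0 <- colMeans(m$counts == 0)
  keep <- frac0 <= zero_frac
  if (!any(keep)) stop("all bins removed by zero_frac = ", zero_frac)
  bins <- new_bin_set(as.data.frame(m$bins)[keep, , drop = FALSE],
                      attr(m$bins, "window_size"))
  new_count_matrix(m$counts[, keep, drop = FALSE], m$cell_ids, bins,
                   m$corrected)
}

#' GC-correct binned counts with a LOESS fit
#'
#' For each cell the raw counts are regressed on bin GC content with LOESS
#' and every count is rescaled by mean(x) / fit(gc), so the corrected profile
#' is flat in GC while the cell's mean count is preserved up to fit error.
#' Fitted values are floored at a small positive epsilon and correction
#' factors clipped to `factor_range` to bound the leverage of sparse GC
#' extremes. Cells with fewer than 10 distinct GC values are left
#' uncorrected with a warning (the fit is ill-posed).
#'
#' @param m a raw `count_matrix` whose bins carry GC fractions.
#' @param loess_span LOESS span (default 0.75).
#' @param factor_range allowed range of per-bin correction factors.
#' @return the `count_matrix` with real-valued corrected counts,
#'   `corrected = TRUE`.
#' @export
gc_correct <- function(m, loess_span = 0.75, factor_range = c(0.2, 5)) {
  stopifnot(inherits(m, "count_matrix"))
  gc <- m$bins$gc
  if (anyNA(gc)) stop("bins carry missing GC; run compute_gc first")
  out <- m$counts * 1.0
  for (i in seq_len(nrow(out))) {
    x <- m$counts[i, ]
    if (length(unique(gc)) < 10) {
      warning("cell ", m$cell_ids[i],
              ": fewer than 10 distinct GC values, correction skipped")
      next
    }
    fit <- stats::loess(x ~ gc, span = loess_span)
    fitted <- stats::predict(fit, gc)
    fitted[is.na(fitted)] <- mean(x)
    fitted <- pmax(fitted, 1e-8 + 1e-3 * mean(x))
    fac <- pmin(pmax(mean(x) / fitted, factor_range[1]), factor_range[2])
    out[i, ] <- x * fac
  }
  new_count_matrix(out, m$cell_ids, m$bins, corrected = TRUE)
}

#' Export a count matrix as MTX plus label sidecars
#'
#' Writes `<prefix>.mtx` (sparse MatrixMarket, bins x cells), and
#' `<prefix>.cells.tsv` / `<prefix>.bins.tsv`.
#'
#' @param m a `count_matrix`.
#' @param prefix output path prefix.
#' @export
export_counts <- function(m, prefix) {
  stopifnot(inherits(m, "count_matrix"))
  Matrix::writeMM(Matrix::Matrix(t(m$counts), sparse = TRUE),
                  paste0(prefix, ".mtx"))
  data.table::fwrite(data.frame(m$cell_ids), paste0(prefix, ".cells.tsv"),
                     sep = "\t", col.names = FALSE)
  data.table::fwrite(data.frame(bin_labels(m$bins)),
                     paste0(prefix, ".bins.tsv"), sep = "\t",
                     col.names = FALSE)
  invisible(prefix)
}
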