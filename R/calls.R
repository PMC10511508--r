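# Copy-state assignment: trimmed segment means, z-score collapse to the
# genome-wide mean, rounded fold change, and the cells x bins state matrix.
# States: 0 = loss, 1 = normal, 2 = gain.

# half-away-from-zero rounding, fixed for reproducibility across platforms
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Trimmed mean of a segment's bin counts
#'
#' Mean after dropping `floor(trim * n)` values from each end of the sorted
#' vector (the lowest and highest `trim` quantile bins). Short segments where
#' trimming would remove everything fall back to the plain mean.
#'
#' @param counts non-empty numeric vector.
#' @param trim fraction in [0, 0.5) trimmed from each end (default 0.1).
#' @export
trimmed_segment_mean <- function(counts, trim = 0.1) {
  if (length(counts) == 0) stop("empty segment")
  stopifnot(trim >= 0, trim < 0.5)
  n <- length(counts)
  k <- floor(trim * n)
  if (2 * k >= n) return(mean(counts))
  mean(sort(counts)[(k + 1):(n - k)])
}

# Tile one cell's chromosome into segments from its kept breakpoints.
# Returns data.frame(chrom, start_bin, end_bin) with chromosome-wide 0-based
# half-open bin ordinals.
segments_from_breakpoints <- function(bins, breakpoints_cell) {
  out <- list()
  for (ch in unique(bins$chrom)) {
    nb <- sum(bins$chrom == ch)
    cuts <- sort(breakpoints_cell$split_index[breakpoints_cell$chrom == ch])
    edges <- c(0L, cuts, nb)
    out[[ch]] <- data.frame(chrom = ch,
                            start_bin = utils::head(edges, -1),
                            end_bin = utils::tail(edges, -1))
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Assign copy states to one cell's segments
#'
#' Each segment gets the trimmed mean of its bin counts. Segments whose
#' z-score (relative to the mean and standard deviation of the cell's
#' segment trimmed means) lies in [-1, 1] have their trimmed mean replaced
#' by the genome-wide mean, i.e. are forced normal. The fold change is then
#' the trimmed mean over the genome-wide trimmed mean, rounded half away
#' from zero: 0 is loss, 1 normal, and >= 2 gain (capped at 2; gains form a
#' single state).
#'
#' @param segment_means numeric vector of segment trimmed means for one cell.
#' @param genome_mean the cell's genome-wide trimmed mean count per bin
#'   (same trim).
#' @return data.frame(trimmed_mean, zscore, fold_change, state).
#' @export
assign_states <- function(segment_means, genome_mean) {
  if (!is.finite(genome_mean) || genome_mean <= 0)
    stop("degenerate cell: genome-wide mean count is not positive")
  mu <- mean(segment_means)
  s <- stats::sd(segment_means)
  z <- if (is.na(s) || s == 0) rep(0, length(segment_means)) else
    (segment_means - mu) / s
  eff <- ifelse(abs(z) <= 1, genome_mean, segment_means)
  fold <- round_half_away(eff / genome_mean)
  state <- pmin(pmax(fold, 0), 2)
  data.frame(trimmed_mean = segment_means, zscore = z,
             fold_change = fold, state = as.integer(state))
}

#' Build the cells x bins copy-state matrix from segment calls
#'
#' Every bin inherits the state of the segment covering it. Segments must
#' tile each cell's binned genome; a gap is an error.
#'
#' @param segments data.frame with columns cell, chrom, start_bin, end_bin
#'   (0-based half-open within-chromosome bin ordinals) and state.
#' @param bins the `bin_set` the segments refer to.
#' @return integer matrix (cells x bins, values 0/1/2) with cell and bin
#'   dimnames.
#' @export
karyotype_matrix <- function(segments, bins) {
  cells <- unique(segments$cell)
  chroms <- unique(bins$chrom)
  offset <- c(0, cumsum(table(factor(bins$chrom, levels = chroms))))
  names(offset) <- c(chroms, "..end")
  k <- matrix(NA_integer_, nrow = length(cells), ncol = nrow(bins),
              dimnames = list(cells, bin_labels(bins)))
  for (i in seq_len(nrow(segments))) {
    sg <- segments[i, ]
    cols <- offset[[sg$chrom]] + seq.int(sg$start_bin + 1L, sg$end_bin)
    k[sg$cell, cols] <- sg$state
  }
  if (anyNA(k)) {
    bad <- which(is.na(k), arr.ind = TRUE)[1, ]
    stop("coverage gap: cell ", cells[bad[1]], ", bin ",
         bin_labels(bins)[bad[2]])
  }
  k
}

#' Write the karyotype matrix as TSV
#'
#' One row per cell, one column per bin (header `chrom:start-end`), values
#' 0 (loss), 1 (normal), 2 (gain).
#'
#' @param k karyotype matrix from [karyotype_matrix()].
#' @param path output path.
#' @export
write_karyotype <- function(k, path) {
  df <- data.frame(cell = rownames(k), k, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
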