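# Binned genome representation: fixed-width windows, GC content, blacklist.
# All coordinates are 0-based half-open (BED convention).

new_bin_set <- function(df, window_size) {
  df <- df[order(match(df$chrom, unique(df$chrom)), df$start), , drop = FALSE]
  df$index <- seq_len(nrow(df)) - 1L
  rownames(df) <- NULL
  structure(df, window_size = as.integer(window_size),
            class = c("bin_set", "data.frame"))
}

#' Read a UCSC-style chrom.sizes table
#'
#' Two tab-separated columns: chromosome name and length in bp. By default
#' only canonical chromosomes (autosomes + X, with or without the "chr"
#' prefix) are retained; mitochondrial and unplaced contigs are dropped
#' because their fragment counts do not reflect nuclear copy number.
#'
#' @param path path to a chrom.sizes file.
#' @param keep_standard drop chrM/chrY and non-canonical contigs.
#' @return named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path, keep_standard = TRUE) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "length"))
  sizes <- structure(as.numeric(dt$length), names = as.character(dt$chrom))
  if (keep_standard) {
    canonical <- c(paste0("chr", c(1:22, "X")), c(1:22, "X"))
    sizes <- sizes[names(sizes) %in% canonical]
  }
  if (anyDuplicated(names(sizes))) stop("duplicated chromosome names")
  if (any(sizes <= 0)) stop("chromosome lengths must be positive")
  sizes
}

#' Partition chromosomes into fixed-width bins
#'
#' Each chromosome is cut into consecutive windows of exactly `window_size`
#' bp; a trailing partial window is dropped so that all bins are the same
#' width (unequal widths would bias the downstream count-distribution
#' comparison).
#'
#' @param chrom_sizes named numeric vector of chromosome lengths (bp), e.g.
#'   from [read_chrom_sizes()].
#' @param window_size bin width in bp (default 100 kb).
#' @return a `bin_set`: data.frame with columns chrom, start, end, gc (NA
#'   until [compute_gc()]), and a contiguous 0-based genome-wide `index`.
#' @examples
#' make_bins(c(chrA = 250000), 100000)
#' @export
make_bins <- function(chrom_sizes, window_size = 100000L) {
  if (is.data.frame(chrom_sizes))
    chrom_sizes <- structure(chrom_sizes[[2]], names = as.character(chrom_sizes[[1]]))
  if (length(chrom_sizes) == 0) stop("empty chrom_sizes")
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be named")
  if (window_size <= 0) stop("window_size must be positive")
  pieces <- lapply(names(chrom_sizes), function(ch) {
    n <- floor(chrom_sizes[[ch]] / window_size)
    if (n < 1) return(NULL)
    start <- (seq_len(n) - 1) * as.numeric(window_size)
    data.frame(chrom = ch, start = start, end = start + window_size,
               gc = NA_real_, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, pieces)
  if (is.null(df) || nrow(df) == 0)
    stop("no bins produced: window_size exceeds every chromosome length")
  new_bin_set(df, window_size)
}

#' Compute per-bin GC content from genome sequence
#'
#' GC fraction is (#G + #C) / (#non-N bases). Bins whose N fraction exceeds
#' `max_n_frac` (including all-N bins) are dropped and the survivors
#' re-indexed, since counts over unsequenced regions are artifacts.
#'
#' @param bins a `bin_set`.
#' @param genome a named character vector of chromosome sequences, a
#'   [Biostrings::DNAStringSet], or a path to a FASTA file.
#' @param max_n_frac drop bins with more than this fraction of N bases.
#' @return the `bin_set` with `gc` filled in.
#' @export
compute_gc <- function(bins, genome, max_n_frac = 0.5) {
  stopifnot(inherits(bins, "bin_set"))
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  missing_chr <- setdiff(unique(bins$chrom), names(genome))
  if (length(missing_chr))
    stop("chromosome(s) absent from genome sequence: ",
         paste(missing_chr, collapse = ", "))
  gc <- nfrac <- numeric(nrow(bins))
  for (ch in unique(bins$chrom)) {
    sel <- which(bins$chrom == ch)
    v <- Biostrings::Views(genome[[ch]], start = bins$start[sel] + 1L,
                           end = bins$end[sel])
    freq <- Biostrings::letterFrequency(v, letters = c("G", "C", "N"))
    width <- bins$end[sel] - bins$start[sel]
    non_n <- width - freq[, "N"]
    gc[sel] <- ifelse(non_n > 0, (freq[, "G"] + freq[, "C"]) / non_n, NA_real_)
    nfrac[sel] <- freq[, "N"] / width
  }
  bins$gc <- gc
  keep <- !is.na(gc) & nfrac <= max_n_frac
  new_bin_set(as.data.frame(bins)[keep, , drop = FALSE],
              attr(bins, "window_size"))
}

#' Remove bins overlapping blacklisted regions
#'
#' Bins overlapping any blacklist interval by at least 1 bp are removed and
#' the survivors re-indexed. Intervals follow the BED convention (0-based
#' half-open), so an interval abutting a bin does not remove it.
#'
#' @param bins a `bin_set`.
#' @param blacklist a data.frame with columns chrom/start/end (0-based
#'   half-open), a [GenomicRanges::GRanges], or a path to a BED file.
#' @return the filtered, re-indexed `bin_set`.
#' @export
apply_blacklist <- function(bins, blacklist) {
  stopifnot(inherits(bins, "bin_set"))
  if (is.character(blacklist) && length(blacklist) == 1) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading BED paths requires the rtracklayer package")
    blacklist <- rtracklayer::import(blacklist)
  }
  if (inherits(blacklist, "GRanges")) {
    blacklist <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(blacklist)),
      start = GenomicRanges::start(blacklist) - 1L,
      end   = GenomicRanges::end(blacklist))
  }
  if (nrow(blacklist) == 0) return(bins)
  if (any(blacklist$end <= blacklist$start))
    stop("malformed blacklist interval: end <= start")
  bl <- GenomicRanges::GRanges(blacklist$chrom,
          IRanges::IRanges(start = blacklist$start + 1L, end = blacklist$end))
  gr <- GenomicRanges::GRanges(bins$chrom,
          IRanges::IRanges(start = bins$start + 1L, end = bins$end))
  hit <- GenomicRanges::countOverlaps(gr, bl) > 0
  new_bin_set(as.data.frame(bins)[!hit, , drop = FALSE],
              attr(bins, "window_size"))
}

#' Export a bin set as BED4
#'
#' Columns: chrom, start, end, genome-wide bin index.
#'
#' @param bins a `bin_set`.
#' @param path output path.
#' @export
export_bins <- function(bins, path) {
  stopifnot(inherits(bins, "bin_set"))
  data.table::fwrite(data.frame(bins$chrom, bins$start, bins$end, bins$index),
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @export
print.bin_set <- function(x, ...) {
  cat(sprintf("bin_set: %d bins of %d bp over %d chromosome(s)\n",
              nrow(x), attr(x, "window_size"), length(unique(x$chrom))))
  invisible(x)
}

bin_labels <- function(bins) {
  sprintf("%s:%d-%d", bins$chrom, as.integer(bins$start), as.integer(bins$end))
}
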