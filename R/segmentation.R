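# Iterative binary segmentation per cell and chromosome, scored by the
# two-sample Anderson-Darling distance, followed by genome-wide pruning.

# Per-split AD distances for one segment, vectorized over all split points.
# The pooled sample is the whole segment for every split, so the distinct
# values z_j, multiplicities l_j and pooled cumulative counts B_j are shared;
# only the left-side cumulative counts M_ij vary with the split.
# A2(i) = 1/(i(L-i)) * sum_j l_j (L*M_ij - i*B_j)^2 / (B_j (L - B_j)),
# over pooled distinct values with B_j < L (the top point, where the pooled
# EDF equals 1, is degenerate and excluded).
ad_all_splits <- function(x) {
  L <- length(x)
  z <- sort(unique(x))
  r <- match(x, z)                       # value rank of each position
  U <- length(z)
  # cumulative count matrix: M[i, j] = #{t <= i : x_t <= z_j}
  ind <- matrix(0, nrow = L, ncol = U)
  ind[cbind(seq_len(L), r)] <- 1
  M <- apply(ind, 2, cumsum)
  if (U > 1) M <- t(apply(M, 1, cumsum)) else M <- matrix(cumsum(ind), ncol = 1)
  B <- M[L, ]
  l <- diff(c(0, B))
  keep <- B < L
  if (!any(keep)) return(rep(0, L - 1))
  i <- seq_len(L - 1)
  D <- L * M[i, keep, drop = FALSE] -
    outer(i, B[keep])
  w <- l[keep] / (B[keep] * (L - B[keep]))
  as.vector((D^2 %*% w) / (i * (L - i)))
}

#' Two-sample Anderson-Darling distance between count vectors
#'
#' The tie-aware discrete form of the two-sample Anderson-Darling statistic:
#' with F, G the right-continuous empirical distribution functions of the two
#' segments, H the pooled one, and the sum running over the pooled distinct
#' values weighted by their pooled multiplicity,
#' \deqn{A^2 = \frac{nm}{N} \sum_j \frac{(F_j - G_j)^2}{H_j (1 - H_j)}
#'   \frac{l_j}{N},}
#' excluding the degenerate top point where H = 1. For all-distinct data this
#' equals the classical continuous two-sample statistic, and it is exactly 0
#' iff the two multisets are identical.
#'
#' @param left,right non-empty numeric vectors of per-bin counts.
#' @return a non-negative scalar.
#' @examples
#' ad_distance(c(5, 5), c(5, 5))     # 0
#' ad_distance(c(0, 0), c(10, 10))   # 2
#' @export
ad_distance <- function(left, right) {
  n <- length(left); m <- length(right)
  if (n == 0 || m == 0) stop("both segments must be non-empty")
  ad_all_splits(c(left, right))[n]
}

#' Best binary split of one segment
#'
#' Evaluates the AD distance between `counts[1:i]` and `counts[(i+1):L]` for
#' every split leaving at least `min_size` bins on each side, and returns the
#' maximizing split (ties broken by the smallest index, for determinism).
#'
#' @param counts numeric vector of per-bin counts for one segment.
#' @param min_size minimum bins per side (default 1).
#' @return list(split_index, ad) where `split_index` is the number of bins in
#'   the left part (i.e. the 0-based ordinal of the first right-hand bin), or
#'   NULL if the segment is shorter than `2 * min_size`.
#' @export
best_split <- function(counts, min_size = 1L) {
  stopifnot(min_size >= 1)
  L <- length(counts)
  if (L < 2 * min_size) return(NULL)
  ad <- ad_all_splits(counts)
  cand <- seq.int(min_size, L - min_size)
  best <- cand[which.max(ad[cand])]
  list(split_index = best, ad = ad[best])
}

#' Segment one chromosome of one cell by iterative binary segmentation
#'
#' Starting from the whole chromosome, the best split of every open segment
#' is computed and the split with the globally largest AD distance is
#' accepted at each iteration (spending the breakpoint budget on the
#' strongest signals first); the chosen segment is divided and the procedure
#' repeats until `k_max` breakpoints have been recorded or no segment can be
#' split.
#'
#' @param counts numeric vector of per-bin counts (one cell, one chromosome).
#' @param k_max maximum number of breakpoints (default 15).
#' @param min_size minimum bins per side of any split (default 1).
#' @return data.frame(split_index, ad, depth) sorted by position;
#'   `split_index` is the chromosome-wide 0-based ordinal of the first bin of
#'   the right segment, `depth` the iteration at which it was found.
#' @export
segment_chromosome <- function(counts, k_max = 15L, min_size = 1L) {
  empty <- data.frame(split_index = integer(), ad = numeric(),
                      depth = integer())
  L <- length(counts)
  if (k_max < 1 || L < 2 * min_size) return(empty)
  # open segments with cached best splits; offsets are 0-based
  segs <- list(list(offset = 0L, counts = counts,
                    best = best_split(counts, min_size)))
  bps <- empty
  for (iter in seq_len(k_max)) {
    ads <- vapply(segs, function(s) if (is.null(s$best)) -Inf else s$best$ad,
                  numeric(1))
    if (!length(ads) || all(!is.finite(ads))) break
    j <- which.max(ads)
    s <- segs[[j]]
    cut <- s$best$split_index
    bps <- rbind(bps, data.frame(split_index = s$offset + cut,
                                 ad = s$best$ad, depth = iter))
    lc <- s$counts[seq_len(cut)]
    rc <- s$counts[(cut + 1):length(s$counts)]
    segs[[j]] <- list(offset = s$offset, counts = lc,
                      best = best_split(lc, min_size))
    segs[[length(segs) + 1]] <- list(offset = s$offset + cut, counts = rc,
                                     best = best_split(rc, min_size))
  }
  bps[order(bps$split_index), , drop = FALSE]
}

#' Segment every chromosome of every cell
#'
#' Runs [segment_chromosome()] on the (rounded) counts of each cell and
#' chromosome of a count matrix. GC-corrected counts are rounded to the
#' nearest integer first: the EDF-based distance tolerates reals, but
#' integer rounding stabilizes tie handling.
#'
#' @param m a `count_matrix` (typically GC-corrected).
#' @param k_max,min_size see [segment_chromosome()].
#' @return data.frame(cell, chrom, split_index, ad, depth, kept) with one row
#'   per breakpoint; `split_index` is the within-chromosome bin ordinal and
#'   `kept` is NA until [prune_breakpoints()].
#' @export
segment_cells <- function(m, k_max = 15L, min_size = 1L) {
  stopifnot(inherits(m, "count_matrix"))
  counts <- round(m$counts)
  chroms <- unique(m$bins$chrom)
  res <- list()
  for (ci in seq_along(m$cell_ids)) {
    for (ch in chroms) {
      sel <- which(m$bins$chrom == ch)
      bp <- segment_chromosome(counts[ci, sel], k_max = k_max,
                               min_size = min_size)
      if (nrow(bp))
        res[[length(res) + 1]] <- data.frame(cell = m$cell_ids[ci],
                                             chrom = ch, bp)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(cell = character(), chrom = character(),
               split_index = integer(), ad = numeric(), depth = integer())
  out$kept <- NA
  rownames(out) <- NULL
  out
}

#' Prune weak breakpoints against the cell's genome-wide mean AD
#'
#' For each cell, the threshold is the mean AD distance of all its recorded
#' breakpoints across the genome (computed before any removal); breakpoints
#' with an AD distance strictly lower than that mean are discarded. Cells
#' without breakpoints are unchanged.
#'
#' @param breakpoints data.frame from [segment_cells()].
#' @return the same data.frame with the logical `kept` column filled in and
#'   per-cell thresholds in attribute `prune_threshold`.
#' @export
prune_breakpoints <- function(breakpoints) {
  bp <- breakpoints
  thr <- vapply(split(bp$ad, bp$cell), mean, numeric(1))
  bp$kept <- as.vector(bp$ad >= thr[as.character(bp$cell)])
  attr(bp, "prune_threshold") <- thr
  bp
}

#' Write the per-cell breakpoint table
#'
#' TSV with one row per breakpoint: cell, chromosome, within-chromosome split
#' bin, genome coordinate of the split, AD distance and kept flag.
#'
#' @param breakpoints pruned breakpoint table.
#' @param bins the `bin_set` the counts were segmented on.
#' @param path output path.
#' @export
write_breakpoints <- function(breakpoints, bins, path) {
  bp <- breakpoints
  coord <- integer(nrow(bp))
  for (ch in unique(bp$chrom)) {
    sel <- bp$chrom == ch
    starts <- bins$start[bins$chrom == ch]
    coord[sel] <- as.integer(starts[bp$split_index[sel] + 1L])
  }
  data.table::fwrite(data.frame(cell = bp$cell, chrom = bp$chrom,
                                split_bin = bp$split_index, coord = coord,
                                ad = bp$ad, kept = bp$kept),
                     path, sep = "\t")
  invisible(path)
}
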