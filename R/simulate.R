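# Synthetic scATAC-seq generator: clone-structured copy-number events on a
# diploid baseline, Poisson emission with log-normal per-cell depth factors
# and a smooth multiplicative GC bias; plus fragment-file export and
# binomial downsampling.

#' Simulation configuration
#'
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @param window_size bin width in bp.
#' @param n_cells number of cells.
#' @param lambda_base mean reads per diploid bin (default 10, the sparse
#'   regime typical of 100-kb scATAC bins).
#' @param depth_sigma sd of the log-normal per-cell depth factor
#'   (default 0.15, i.e. roughly +/-15% depth variation across cells).
#' @param gc_range per-bin GC fractions are drawn uniformly from this range
#'   (default 0.3-0.6, the bulk of the human genome).
#' @param gc_bias `c(scale, center, curvature)` of the multiplicative bias
#'   curve `scale + curvature * (gc - center)^2`, normalized to mean 1 over
#'   bins. The default is a mild unimodal curve peaking at GC 0.45.
#' @param seed integer seed fixing all randomness.
#' @return a `sim_config` list.
#' @export
sim_config <- function(chrom_sizes, window_size = 100000L, n_cells = 100L,
                       lambda_base = 10, depth_sigma = 0.15,
                       gc_range = c(0.3, 0.6),
                       gc_bias = c(scale = 1.1, center = 0.45,
                                   curvature = -6),
                       seed = 1L) {
  stopifnot(lambda_base > 0, n_cells >= 1)
  structure(list(chrom_sizes = chrom_sizes, window_size = window_size,
                 n_cells = as.integer(n_cells), lambda_base = lambda_base,
                 depth_sigma = depth_sigma, gc_range = gc_range,
                 gc_bias = gc_bias, seed = as.integer(seed)),
            class = "sim_config")
}

#' Clone specification
#'
#' A clone is a population fraction plus a set of non-overlapping
#' copy-number events on a diploid (copy state 2) baseline. Event
#' coordinates are within-chromosome bin ordinals, 0-based half-open.
#'
#' @param label clone name.
#' @param proportion fraction of cells in (0, 1].
#' @param events data.frame(chrom, start_bin, end_bin, copy_state) with
#'   copy_state in {1, 2, 3}; NULL for a euploid clone.
#' @export
clone_spec <- function(label, proportion, events = NULL) {
  if (is.null(events))
    events <- data.frame(chrom = character(), start_bin = integer(),
                         end_bin = integer(), copy_state = integer())
  stopifnot(proportion > 0, proportion <= 1,
            all(events$copy_state %in% 1:3),
            all(events$end_bin > events$start_bin))
  events$start_bin <- as.integer(events$start_bin)
  events$end_bin <- as.integer(events$end_bin)
  events$copy_state <- as.integer(events$copy_state)
  for (ch in unique(events$chrom)) {
    ev <- events[events$chrom == ch, , drop = FALSE]
    ev <- ev[order(ev$start_bin), , drop = FALSE]
    if (nrow(ev) > 1 && any(utils::head(ev$end_bin, -1) >
                            utils::tail(ev$start_bin, -1)))
      stop("overlapping events within clone ", label)
  }
  structure(list(label = label, proportion = proportion, events = events),
            class = "clone_spec")
}

#' Simulate a clone-structured count matrix with known truth
#'
#' Cell c of clone g draws its count in bin t from
#' `Poisson(d_c * lambda_base * copy_state(g, t) / 2 * bias(gc_t))` with
#' `d_c ~ LogNormal(0, depth_sigma)`, so a 3-copy region carries 1.5x and a
#' 1-copy region 0.5x the diploid rate. Fully reproducible for a given
#' config seed.
#'
#' @param cfg a [sim_config()].
#' @param clones list of [clone_spec()]; proportions must sum to 1.
#' @return list with `counts` (raw `count_matrix`, bins carrying the
#'   simulated GC), `truth` (cells x bins matrix of 0/1/2), and `clone`
#'   (named character vector of generating clone labels).
#' @export
simulate_counts <- function(cfg, clones) {
  stopifnot(inherits(cfg, "sim_config"))
  props <- vapply(clones, `[[`, numeric(1), "proportion")
  if (abs(sum(props) - 1) > 1e-8)
    stop("clone proportions must sum to 1 (got ", sum(props), ")")
  set.seed(cfg$seed)
  bins <- make_bins(cfg$chrom_sizes, cfg$window_size)
  nb <- nrow(bins)
  bins$gc <- stats::runif(nb, cfg$gc_range[1], cfg$gc_range[2])
  bias <- cfg$gc_bias[[1]] + cfg$gc_bias[[3]] * (bins$gc - cfg$gc_bias[[2]])^2
  bias <- pmax(bias, 0.05)
  bias <- bias / mean(bias)
  # per-clone copy-state rows on the {1,2,3} scale
  clone_states <- vapply(clones, function(cl) {
    s <- rep(2L, nb)
    if (nrow(cl$events)) for (i in seq_len(nrow(cl$events))) {
      ev <- cl$events[i, ]
      sel <- which(bins$chrom == ev$chrom)
      if (ev$end_bin > length(sel)) stop("event beyond chromosome ", ev$chrom)
      s[sel[(ev$start_bin + 1):ev$end_bin]] <- ev$copy_state
    }
    s
  }, integer(nb))
  # deterministic clone sizes from proportions
  sizes <- diff(round(cumsum(c(0, props)) * cfg$n_cells))
  clone_of <- rep(seq_along(clones), sizes)
  cell_ids <- sprintf("cell_%04d", seq_len(cfg$n_cells))
  d <- stats::rlnorm(cfg$n_cells, 0, cfg$depth_sigma)
  counts <- matrix(0L, nrow = cfg$n_cells, ncol = nb)
  for (c in seq_len(cfg$n_cells)) {
    mu <- d[c] * cfg$lambda_base * clone_states[, clone_of[c]] / 2 * bias
    counts[c, ] <- stats::rpois(nb, mu)
  }
  truth <- t(clone_states)[clone_of, , drop = FALSE] - 1L
  dimnames(truth) <- list(cell_ids, bin_labels(bins))
  clone_labels <- vapply(clones, `[[`, character(1), "label")[clone_of]
  names(clone_labels) <- cell_ids
  list(counts = new_count_matrix(counts, cell_ids, bins, corrected = FALSE),
       truth = truth, clone = clone_labels)
}

#' Write a count matrix as a synthetic fragments file
#'
#' Emits, for every cell and bin, as many fragment records as the count,
#' with deterministic start offsets chosen so every fragment midpoint falls
#' inside its bin; round-tripping through [count_fragments()] on the same
#' bins recovers the matrix exactly. Gzipped output when the path ends in
#' `.gz`.
#'
#' @param m a raw `count_matrix`.
#' @param path output fragments.tsv(.gz) path.
#' @param frag_len fragment length in bp (default 200, clipped to fit the
#'   bin).
#' @export
write_fragments <- function(m, path, frag_len = 200L) {
  stopifnot(inherits(m, "count_matrix"), !m$corrected)
  w <- attr(m$bins, "window_size")
  fl <- max(2L, min(frag_len, w - 2L))
  idx <- which(m$counts > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    con <- if (endsWith(path, ".gz")) gzfile(path, "w") else file(path, "w")
    writeLines(character(0), con)
    close(con)
    return(invisible(path))
  }
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  n <- m$counts[idx]
  cell <- rep(m$cell_ids[idx[, 1]], n)
  bin_row <- rep(idx[, 2], n)
  within <- unlist(lapply(n, seq_len)) - 1L
  span <- max(1L, w - fl - 1L)
  start <- m$bins$start[bin_row] + (within * 37L) %% span
  dt <- data.table::data.table(chrom = m$bins$chrom[bin_row],
                               start = as.integer(start),
                               end = as.integer(start + fl),
                               barcode = cell, dup_count = 1L)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE,
                     compress = if (endsWith(path, ".gz")) "gzip" else "none")
  invisible(path)
}

#' Binomial downsampling of a count matrix
#'
#' Every count is replaced by a Binomial(count, rate) draw, emulating
#' retaining each read independently with probability `rate`.
#'
#' @param m a raw `count_matrix`.
#' @param rate retention probability in (0, 1].
#' @param seed integer seed.
#' @export
downsample_counts <- function(m, rate, seed = 1L) {
  stopifnot(inherits(m, "count_matrix"))
  if (!(rate > 0 && rate <= 1)) stop("rate must be in (0, 1]")
  if (rate == 1) return(m)
  set.seed(seed)
  v <- m$counts
  v[] <- stats::rbinom(length(v), as.vector(v), rate)
  new_count_matrix(v, m$cell_ids, m$bins, m$corrected)
}

#' Reference simulation: two balanced aneuploid clones over two chromosomes
#'
#' The package's benchmark study condition: 200 cells, two chromosomes of
#' 500 bins each (100-kb windows), lambda_base 10 reads per diploid bin, and
#' two equal clones. Each clone carries six private 60-bin events (three
#' losses and three gains, alternating across the two chromosomes) at loci
#' disjoint from the other clone's, so that (a) every cell's genome-wide
#' mean count stays at the diploid level (gains and losses balance), and
#' (b) the two clones are distinguishable at every event locus. Mild
#' unimodal GC bias.
#'
#' @param seed integer seed.
#' @param n_cells number of cells (default 200).
#' @return list(cfg, clones) ready for [simulate_counts()].
#' @export
reference_sim <- function(seed = 1L, n_cells = 200L) {
  cfg <- sim_config(chrom_sizes = c(chrA = 5e7, chrB = 5e7),
                    window_size = 100000L, n_cells = n_cells,
                    lambda_base = 10, seed = seed)
  clones <- list(
    clone_spec("A", 0.5, data.frame(
      chrom = rep(c("chrA", "chrB"), each = 3),
      start_bin = c(50L, 200L, 350L, 60L, 210L, 360L),
      end_bin   = c(110L, 260L, 410L, 120L, 270L, 420L),
      copy_state = c(1L, 3L, 1L, 3L, 1L, 3L))),
    clone_spec("B", 0.5, data.frame(
      chrom = rep(c("chrA", "chrB"), each = 3),
      start_bin = c(120L, 270L, 420L, 130L, 280L, 430L),
      end_bin   = c(180L, 330L, 480L, 190L, 340L, 490L),
      copy_state = c(3L, 1L, 3L, 1L, 3L, 1L))))
  list(cfg = cfg, clones = clones)
}
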