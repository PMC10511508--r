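# Clone structure: Ward clustering of karyotypes and the karyogram heatmap.

#' Cluster cells into karyotype clones
#'
#' Agglomerative clustering of the cells' copy-state rows (codes 0/1/2 as
#' given, not one-hot) with Euclidean distance and Ward linkage, cut into
#' `n_clusters` flat clusters. Deterministic for a given input.
#'
#' @param k karyotype matrix (cells x bins, values 0/1/2).
#' @param n_clusters number of flat clusters to cut.
#' @return a `clone_assignment`: list with `labels` (named integer vector,
#'   contiguous from 1 in order of first appearance), `tree` (the hclust
#'   object) and `n_clusters`.
#' @export
cluster_karyotypes <- function(k, n_clusters) {
  if (nrow(k) < 2) stop("need at least 2 cells to cluster")
  if (n_clusters > nrow(k))
    stop("n_clusters exceeds the number of cells")
  tree <- stats::hclust(stats::dist(k, method = "euclidean"),
                        method = "ward.D2")
  raw <- stats::cutree(tree, k = n_clusters)
  labels <- match(raw, unique(raw))          # contiguous 1..k, first-seen order
  names(labels) <- rownames(k)
  structure(list(labels = labels, tree = tree, n_clusters = n_clusters),
            class = "clone_assignment")
}

#' @export
print.clone_assignment <- function(x, ...) {
  cat("clone_assignment:", length(x$labels), "cells in", x$n_clusters,
      "clone(s)\n")
  print(table(x$labels))
  invisible(x)
}

#' Write the cell-to-clone table as TSV
#'
#' @param clones a `clone_assignment`.
#' @param path output path.
#' @export
write_clones <- function(clones, path) {
  data.table::fwrite(data.frame(cell = names(clones$labels),
                                clone = unname(clones$labels)),
                     path, sep = "\t")
  invisible(path)
}

#' Karyogram heatmap of copy states
#'
#' Every row is a cell (ordered by the clustering dendrogram when available),
#' every column a bin; loss/normal/gain are drawn in blue/grey/red with
#' chromosome boundaries marked. With a clone assignment, a clone annotation
#' bar is drawn on the left.
#'
#' @param k karyotype matrix (cells x bins, values 0/1/2) with
#'   `chrom:start-end` column names.
#' @param clones optional `clone_assignment` from [cluster_karyotypes()];
#'   its dendrogram fixes the row order.
#' @param path PNG output path; NULL draws on the current device.
#' @param width,height device size in pixels.
#' @return the path, invisibly.
#' @export
plot_karyogram <- function(k, clones = NULL, path = NULL,
                           width = 900, height = 600) {
  if (is.null(dim(k)) || nrow(k) == 0 || ncol(k) == 0)
    stop("empty karyotype matrix")
  ord <- seq_len(nrow(k))
  if (!is.null(clones)) ord <- clones$tree$order
  else if (nrow(k) >= 3)
    ord <- stats::hclust(stats::dist(k), method = "ward.D2")$order
  chrom <- sub(":.*$", "", colnames(k))
  bounds <- which(diff(match(chrom, unique(chrom))) != 0)
  cols <- c("#2166AC", "#E6E6E6", "#B2182B")   # loss, normal, gain
  if (!is.null(path)) {
    ok <- tryCatch({ grDevices::png(path, width = width, height = height); TRUE },
                   error = function(e) FALSE)
    if (!ok) stop("cannot write image to ", path)
    on.exit(grDevices::dev.off())
  }
  if (!is.null(clones)) {
    graphics::layout(matrix(1:2, nrow = 1), widths = c(1, 14))
    graphics::par(mar = c(4, 1, 3, 0))
    graphics::image(t(matrix(as.integer(clones$labels[ord]), ncol = 1)),
                    col = grDevices::hcl.colors(max(clones$labels), "Dark 3"),
                    axes = FALSE)
    graphics::mtext("clone", side = 3, line = 0.5, cex = 0.8)
    graphics::par(mar = c(4, 0.5, 3, 1))
  } else {
    graphics::par(mar = c(4, 2, 3, 1))
  }
  graphics::image(x = seq_len(ncol(k)), y = seq_len(nrow(k)),
                  z = t(k[ord, , drop = FALSE]), zlim = c(0, 2),
                  col = cols, axes = FALSE, xlab = "bin", ylab = "",
                  main = "Copy-number karyogram")
  graphics::abline(v = bounds + 0.5, col = "black", lwd = 0.8)
  mids <- tapply(seq_along(chrom), factor(chrom, levels = unique(chrom)), mean)
  graphics::axis(1, at = mids, labels = names(mids), tick = FALSE, cex.axis = 0.8)
  invisible(path)
}
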