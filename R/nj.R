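# Neighbor joining (Saitou & Nei, with the Studier-Keppler Q criterion).
#
# The output is unrooted (trifurcating root). Determinism: leaves are
# processed in label-sorted order and Q-matrix ties resolve to the smallest
# (i, j) index pair in that ordering; merged nodes append after the leaves.
# Negative intermediate branch lengths are clamped to zero with the deficit
# shifted to the sister edge, preserving the joined pair's path length.

#' Neighbor-joining tree from a distance matrix
#'
#' @param D Symmetric numeric matrix with zero diagonal and finite entries;
#'   row/column names are the taxon labels.
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(D) {
  if (!is.matrix(D)) D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining needs at least three taxa")
  if (is.null(rownames(D))) stop("distance matrix must carry taxon labels")
  if (any(!is.finite(D))) stop("distance matrix has non-finite entries")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(D < 0)) stop("distance matrix has negative entries")
  ord <- order(rownames(D))
  D <- D[ord, ord]
  # active nodes are newick substrings
  nodes <- rownames(D)
  fmt <- function(x) sprintf("%.15g", max(x, 0))
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    dij <- D[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dij - li
    if (li < 0) { li <- 0; lj <- dij }
    if (lj < 0) { lj <- 0; li <- dij }
    newdist <- (D[i, ] + D[j, ] - dij) / 2
    newdist <- pmax(newdist[-c(i, j)], 0)
    label <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt(li), nodes[j], fmt(lj))
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newdist),
               c(newdist, 0))
    nodes <- c(nodes[keep], label)
    rownames(D) <- colnames(D) <- nodes
  }
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nodes[1], fmt(la),
                 nodes[2], fmt(lb), nodes[3], fmt(lc))
  ape::read.tree(text = txt)
}
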