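# Bootstrap replication and strict majority-rule consensus.

#' Infer a tree from an alignment
#'
#' Corrected-distance neighbor joining ([seq_distance_matrix()] +
#' [neighbor_joining()]); the desk-scale, deterministic stand-in for a
#' maximum-likelihood search. Externally computed trees (e.g. ML trees in
#' Newick) can enter the downstream statistics via [read_newick()] instead.
#'
#' @param x A [msa()].
#' @param type `"protein"` or `"nucleotide"`.
#' @return An unrooted `ape::phylo` tree.
#' @export
tree_from_msa <- function(x, type = c("protein", "nucleotide")) {
  neighbor_joining(seq_distance_matrix(x, type))
}

#' Bootstrap replicate trees from an alignment
#'
#' Each replicate resamples alignment columns with replacement to the
#' original column count, then rebuilds the corrected-distance
#' neighbor-joining tree. Fully reproducible from `seed`.
#'
#' @param x A [msa()].
#' @param n Number of replicates (default 100).
#' @param seed RNG seed (default 1).
#' @param type `"protein"` or `"nucleotide"`.
#' @return List of `ape::phylo` trees, length `n`.
#' @export
bootstrap_trees <- function(x, n = 100L, seed = 1L,
                            type = c("protein", "nucleotide")) {
  type <- match.arg(type)
  if (n < 1L) stop("need at least one bootstrap replicate")
  if (x$n_columns < 2L) stop("alignment has fewer than two columns")
  m <- msa_matrix(x)
  L <- ncol(m)
  with_seed(seed, {
    lapply(seq_len(n), function(b) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_msa <- msa(stats::setNames(
        apply(m[, cols, drop = FALSE], 1, paste, collapse = ""),
        rownames(m)), source = sprintf("bootstrap%03d", b))
      tree_from_msa(rep_msa, type)
    })
  })
}

#' Strict majority-rule consensus tree
#'
#' Bipartitions occurring in strictly more than `threshold * n` input trees
#' are retained; each retained edge carries support
#' `round(100 * frequency)` (half-up) and the mean of that bipartition's
#' branch lengths over the trees containing it. Everything else collapses
#' to polytomies. Pendant edges get mean lengths over all trees.
#'
#' @param trees List of `ape::phylo` trees on one leaf set.
#' @param threshold Fraction in `[0.5, 1)` (default 0.5, i.e. strict
#'   majority).
#' @return An `ape::phylo` tree with integer supports as node labels.
#' @export
majority_consensus <- function(trees, threshold = 0.5) {
  if (!length(trees)) stop("no trees supplied")
  if (threshold < 0.5 || threshold >= 1)
    stop("consensus threshold must lie in [0.5, 1)")
  leaves <- sort(trees[[1]]$tip.label)
  for (t in trees) if (!setequal(t$tip.label, leaves))
    stop("trees disagree on the leaf set")
  n <- length(trees)
  counts <- new.env(parent = emptyenv())
  lens <- new.env(parent = emptyenv())
  for (t in trees) {
    s <- tree_splits(t)
    # a bipartition occurs at most once per tree; guard all the same
    s <- s[!duplicated(s$key), , drop = FALSE]
    for (r in seq_len(nrow(s))) {
      k <- s$key[r]
      counts[[k]] <- (counts[[k]] %||% 0L) + 1L
      lens[[k]] <- c(lens[[k]], s$length[r])
    }
  }
  nt <- length(leaves)
  all_keys <- ls(counts)
  sizes <- lengths(strsplit(all_keys, "\t", fixed = TRUE))
  nontrivial <- all_keys[sizes >= 2L & sizes <= nt - 2L]
  retained <- nontrivial[vapply(nontrivial, function(k)
    counts[[k]] > threshold * n, TRUE)]
  ref <- leaves[1]
  # sides exclude the reference leaf by canonicalization, so retained
  # bipartitions are clades of the tree rooted at ref's pendant edge
  clades <- strsplit(retained, "\t", fixed = TRUE)
  ord <- order(lengths(clades), decreasing = TRUE)
  clades <- clades[ord]
  retained <- retained[ord]
  # ":length" suffix, empty when the input trees carry no lengths
  len_suffix <- function(k) {
    v <- suppressWarnings(mean(lens[[k]], na.rm = TRUE))
    if (!is.finite(v)) "" else sprintf(":%.15g", v)
  }
  support <- function(k) round_half_up(100 * counts[[k]] / n)
  leaf_key <- function(l) {
    if (l == ref) paste(sort(setdiff(leaves, ref)), collapse = "\t")
    else l
  }
  # parent of clade i = smallest retained clade strictly containing it
  nc <- length(clades)
  parent <- rep(0L, nc)
  if (nc > 1L) for (i in seq_len(nc)) {
    for (j in seq_len(nc)) {
      if (j == i) next
      if (length(clades[[j]]) > length(clades[[i]]) &&
          all(clades[[i]] %in% clades[[j]])) {
        if (parent[i] == 0L ||
            length(clades[[j]]) < length(clades[[parent[i]]]))
          parent[i] <- j
      }
    }
  }
  leaf_parent <- vapply(setdiff(leaves, ref), function(l) {
    best <- 0L
    for (j in seq_len(nc)) {
      if (l %in% clades[[j]] &&
          (best == 0L || length(clades[[j]]) < length(clades[[best]])))
        best <- j
    }
    best
  }, 0L)
  leaf_str <- function(l) sprintf("%s%s", l, len_suffix(leaf_key(l)))
  clade_str <- function(i) {
    kids_c <- which(parent == i)
    kids_l <- names(leaf_parent)[leaf_parent == i]
    inner <- paste(c(vapply(kids_c, clade_str, ""),
                     vapply(kids_l, leaf_str, "")), collapse = ",")
    sprintf("(%s)%d%s", inner, support(retained[i]),
            len_suffix(retained[i]))
  }
  top_c <- which(parent == 0L)
  top_l <- names(leaf_parent)[leaf_parent == 0L]
  txt <- sprintf("(%s);", paste(c(leaf_str(ref),
                                  vapply(top_c, clade_str, ""),
                                  vapply(top_l, leaf_str, "")),
                                collapse = ","))
  ape::read.tree(text = txt)
}
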