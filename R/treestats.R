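# Tree statistics and congruence: bipartition handling, branch-length sums,
# bootstrap-support audits, Robinson-Foulds distances, group monophyly.
# All comparisons use unrooted semantics: a bipartition is canonicalized to
# the side not containing the alphabetically first leaf label.

# Split table of a tree: one row per edge, with the canonical side.
tree_splits <- function(tree) {
  nt <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1]
  post <- ape::reorder.phylo(tree, "postorder")
  clade <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) clade[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1]; ch <- post$edge[e, 2]
    clade[[p]] <- c(clade[[p]], clade[[ch]])
  }
  child <- tree$edge[, 2]
  side <- lapply(child, function(ch) {
    s <- clade[[ch]]
    if (ref %in% s) setdiff(tree$tip.label, s) else s
  })
  key <- vapply(side, function(s) paste(sort(s), collapse = "\t"), "")
  size <- lengths(side)
  sup <- rep(NA_real_, length(child))
  if (!is.null(tree$node.label)) {
    internal <- child > nt
    sup[internal] <- suppressWarnings(
      as.numeric(tree$node.label[child[internal] - nt]))
  }
  data.frame(key = key, size = size,
             length = if (is.null(tree$edge.length))
               NA_real_ else tree$edge.length,
             support = sup,
             trivial = size <= 1L | size >= nt - 1L,
             stringsAsFactors = FALSE)
}

nontrivial_keys <- function(tree) {
  s <- tree_splits(tree)
  unique(s$key[!s$trivial])
}

#' Sum of branch lengths of a tree
#'
#' Arithmetic sum over every edge, terminal edges included.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @return Numeric scalar.
#' @export
sum_branch_lengths <- function(tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree has absent branch length(s)")
  sum(tree$edge.length)
}

#' Audit bootstrap supports of a tree
#'
#' Counts internal nodes whose support reaches `threshold` (integer
#' percent) and reports the support range.
#'
#' @param tree An `ape::phylo` with numeric internal node labels.
#' @param threshold Integer percent (default 70).
#' @return List `count`, `n_supported`, `min`, `max`.
#' @export
count_supports_ge <- function(tree, threshold = 70) {
  sup <- tree_supports(tree)
  sup <- sup[!is.na(sup)]
  if (!length(sup)) {
    warning("tree carries no numeric supports")
    return(list(count = 0L, n_supported = 0L, min = NA_real_,
                max = NA_real_))
  }
  list(count = sum(sup >= threshold), n_supported = length(sup),
       min = min(sup), max = max(sup))
}

#' Robinson-Foulds distance between two trees
#'
#' Size of the symmetric difference of the nontrivial bipartition sets,
#' plus the normalization by the total number of nontrivial bipartitions in
#' both trees.
#'
#' @param t1,t2 `ape::phylo` trees on the same leaf set.
#' @return List `rf` (integer), `normalized` (fraction in \[0, 1\]).
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    only1 <- setdiff(t1$tip.label, t2$tip.label)
    only2 <- setdiff(t2$tip.label, t1$tip.label)
    stop("leaf sets differ; only in first: ",
         paste(only1, collapse = ", "), "; only in second: ",
         paste(only2, collapse = ", "))
  }
  s1 <- nontrivial_keys(t1)
  s2 <- nontrivial_keys(t2)
  rf <- length(setdiff(s1, s2)) + length(setdiff(s2, s1))
  denom <- length(s1) + length(s2)
  list(rf = as.integer(rf),
       normalized = if (denom == 0L) 0 else rf / denom)
}

#' Assess monophyly of reference groups on a tree
#'
#' A group is monophyletic (unrooted sense) when some bipartition separates
#' exactly its members from all other taxa. Singleton groups (and groups
#' covering all but at most one taxon) are trivially monophyletic and
#' flagged as such. The supporting edge's bootstrap value is reported when
#' present.
#'
#' @param tree An `ape::phylo` tree.
#' @param groups Data frame with columns `label`, `group`, or a named
#'   character vector `label -> group`.
#' @return List with `per_group` (data frame `group`, `n`, `monophyletic`,
#'   `trivial`, `support`) and `n_monophyletic`.
#' @export
assess_group_monophyly <- function(tree, groups) {
  if (is.character(groups))
    groups <- data.frame(label = names(groups), group = unname(groups),
                         stringsAsFactors = FALSE)
  absent <- setdiff(groups$label, tree$tip.label)
  if (length(absent))
    stop("group map references taxa absent from the tree: ",
         paste(absent, collapse = ", "))
  nt <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1]
  splits <- tree_splits(tree)
  per <- lapply(split(groups$label, groups$group), function(members) {
    n <- length(members)
    if (n <= 1L || n >= nt - 1L)
      return(data.frame(n = n, monophyletic = TRUE, trivial = TRUE,
                        support = NA_real_))
    side <- if (ref %in% members) setdiff(tree$tip.label, members)
            else members
    key <- paste(sort(side), collapse = "\t")
    hit <- match(key, splits$key)
    data.frame(n = n, monophyletic = !is.na(hit), trivial = FALSE,
               support = if (is.na(hit)) NA_real_ else splits$support[hit])
  })
  tab <- cbind(data.frame(group = names(per), stringsAsFactors = FALSE),
               do.call(rbind, per))
  rownames(tab) <- NULL
  list(per_group = tab, n_monophyletic = sum(tab$monophyletic))
}

#' Read a two-column group map
#'
#' TSV with columns `label`, `group` (no header required; a `label` header
#' row is tolerated).
#'
#' @param path File path.
#' @return Data frame `label`, `group`.
#' @export
read_group_map <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE,
                         col.names = c("label", "group"))
  if (nrow(x) && x$label[1] == "label") x <- x[-1, , drop = FALSE]
  rownames(x) <- NULL
  x
}
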