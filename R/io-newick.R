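# Newick tree exchange, on top of ape's phylo container.
#
# Bootstrap supports travel as integer internal-node labels (the dialect
# RAxML and Geneious emit); branch lengths survive round-trips to at least
# ten significant digits.

#' Read a Newick tree
#'
#' Numeric internal-node labels are interpreted as integer-percent bootstrap
#' supports and kept in `node.label`.
#'
#' @param x Newick text (ends in `;`) or the path of a file holding one tree.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(x) {
  txt <- if (length(x) == 1L && !grepl(";", x) && file.exists(x))
    paste(readLines(x, warn = FALSE), collapse = "") else x
  if (length(txt) != 1L || !nzchar(trimws(txt)))
    stop("expected a single Newick string or file")
  no_quote <- gsub("'[^']*'", "", txt)
  if (sum(strsplit(no_quote, "")[[1]] == "(") !=
      sum(strsplit(no_quote, "")[[1]] == ")"))
    stop("unbalanced parentheses in Newick input")
  tr <- ape::read.tree(text = txt)
  if (is.null(tr)) stop("malformed Newick input")
  if (anyDuplicated(tr$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]),
               collapse = ", "))
  tr
}

#' Write a tree as Newick text
#'
#' @param tree An `ape::phylo` tree.
#' @param path Optional file; when given, the text is also written there.
#' @return The Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

# Numeric supports of internal nodes (NA where absent / non-numeric).
tree_supports <- function(tree) {
  if (is.null(tree$node.label)) return(numeric(0))
  suppressWarnings(as.numeric(tree$node.label))
}
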