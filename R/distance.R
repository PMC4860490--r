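# Corrected pairwise distances from alignments.
#
# The mismatch fraction p is computed over columns where both rows are
# ungapped, then corrected: Kimura's protein formula
# d = -ln(1 - p - 0.2 p^2), or Jukes-Cantor d = -(3/4) ln(1 - (4/3) p) for
# nucleotides. Pairs past the correction's domain (saturated) are set to
# twice the largest finite corrected distance in the matrix, with a warning.

correct_distance <- function(p, type = c("protein", "nucleotide")) {
  type <- match.arg(type)
  if (type == "protein") {
    arg <- 1 - p - 0.2 * p^2
  } else {
    arg <- 1 - (4 / 3) * p
  }
  ifelse(arg > 0, -log(arg) * if (type == "protein") 1 else 0.75, Inf)
}

#' Corrected distance matrix from an alignment
#'
#' @param x A [msa()].
#' @param type `"protein"` (Kimura correction) or `"nucleotide"`
#'   (Jukes-Cantor).
#' @return Symmetric numeric matrix with zero diagonal, labelled by taxon.
#' @export
seq_distance_matrix <- function(x, type = c("protein", "nucleotide")) {
  type <- match.arg(type)
  if (length(x$labels) < 3L) stop("need at least three rows")
  m <- msa_matrix(x)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    shared <- m[i, ] != "-" & m[j, ] != "-"
    ns <- sum(shared)
    if (ns == 0L)
      stop("rows ", rownames(m)[i], " and ", rownames(m)[j],
           " share no ungapped columns")
    p <- sum(m[i, shared] != m[j, shared]) / ns
    D[i, j] <- D[j, i] <- correct_distance(p, type)
  }
  if (any(!is.finite(D))) {
    mx <- max(D[is.finite(D)])
    D[!is.finite(D)] <- 2 * mx
    warning("saturated distance(s) replaced by twice the largest finite ",
            "corrected distance")
  }
  D
}
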