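# Pairwise and profile alignment: global affine-gap (Gotoh) dynamic
# programming over substitution-matrix column scores, with an optional
# free-end-gap policy. The DP inner loop lives in src/align.cpp.

#' Alignment parameter set
#'
#' Gap costs are signed contributions to the score: opening a gap run costs
#' `gap_open + gap_extend` for its first element and `gap_extend` for each
#' further element. The protein defaults reproduce the published protocol
#' (BLOSUM matrix, gap creation -10, extension -0.1 per element, global with
#' free end gaps); the nucleotide defaults use the +5/-4 scheme with
#' opening 15 and extension 6.66 costs.
#'
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @param matrix Substitution matrix id (see [substitution_matrix()]).
#' @param gap_open,gap_extend Signed gap costs (must be `<= 0`).
#' @param free_end_gaps Leading/trailing gaps cost nothing when `TRUE`.
#' @return An object of class `align_params`.
#' @export
align_params <- function(alphabet = c("protein", "nucleotide"),
                         matrix = NULL, gap_open = NULL, gap_extend = NULL,
                         free_end_gaps = TRUE) {
  alphabet <- match.arg(alphabet)
  if (is.null(matrix))
    matrix <- if (alphabet == "protein") "BLOSUM62" else "NUC.5-4"
  if (is.null(gap_open))
    gap_open <- if (alphabet == "protein") -10 else -15
  if (is.null(gap_extend))
    gap_extend <- if (alphabet == "protein") -0.1 else -6.66
  if (gap_open > 0 || gap_extend > 0)
    stop("gap costs must be negative contributions to the score")
  S <- substitution_matrix(matrix)
  structure(list(alphabet = alphabet, matrix = matrix, S = S,
                 gap_open = gap_open, gap_extend = gap_extend,
                 free_end_gaps = isTRUE(free_end_gaps)),
            class = "align_params")
}

# residues of the scoring alphabet for an align_params (excluding '*')
params_alphabet <- function(params) {
  ab <- rownames(params$S)
  setdiff(ab, "*")
}

# one-hot profile (K x L) for a sequence under params' alphabet
seq_profile <- function(seq, params) {
  ab <- rownames(params$S)
  ch <- split1(toupper(seq))
  idx <- match(ch, ab)
  if (anyNA(idx))
    stop("sequence contains symbols outside the ", params$alphabet,
         " alphabet: ", paste(unique(ch[is.na(idx)]), collapse = ", "))
  P <- matrix(0, nrow = length(ab), ncol = length(ch))
  P[cbind(idx, seq_along(idx))] <- 1
  P
}

# column-vs-column expected substitution scores for two profiles
profile_scores <- function(PA, PB, S) {
  crossprod(PA, S %*% PB)
}

#' Optimal global pairwise alignment
#'
#' Affine-gap global alignment under an [align_params()] scoring scheme.
#' Identity is matches divided by total alignment length, gap columns
#' included.
#'
#' @param a,b Unaligned sequences (single strings).
#' @param params An [align_params()].
#' @return List with `alignment` (two gapped strings, named after the
#'   inputs when they are named), `score`, and `identity`.
#' @export
pairwise_align <- function(a, b, params = align_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence")
  PA <- seq_profile(a, params)
  PB <- seq_profile(b, params)
  sc <- profile_scores(PA, PB, params$S)
  res <- .gotoh_align(sc, params$gap_open, params$gap_extend,
                      params$free_end_gaps)
  ca <- split1(toupper(a))
  cb <- split1(toupper(b))
  ga <- ifelse(res$a_idx == 0L, "-", ca[pmax(res$a_idx, 1L)])
  gb <- ifelse(res$b_idx == 0L, "-", cb[pmax(res$b_idx, 1L)])
  matches <- sum(ga == gb & ga != "-")
  out <- c(paste(ga, collapse = ""), paste(gb, collapse = ""))
  nms <- c(names(a), names(b))
  if (length(nms) == 2L) names(out) <- nms
  list(alignment = out, score = res$score,
       identity = matches / length(ga))
}

# ---- the MSA container ---------------------------------------------------

#' Construct a multiple sequence alignment object
#'
#' @param seqs Named character vector of equal-length gapped rows.
#' @param source Label recording which aligner/parameter set produced it.
#' @return Object of class `glyco_msa` with fields `labels`, `seqs`,
#'   `n_columns`, `source`.
#' @export
msa <- function(seqs, source = "unknown") {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("alignment rows must carry unique labels")
  w <- unique(nchar(seqs))
  if (length(w) != 1L) stop("alignment rows differ in length")
  structure(list(labels = names(seqs), seqs = seqs, n_columns = w,
                 source = source),
            class = "glyco_msa")
}

#' @export
print.glyco_msa <- function(x, ...) {
  cat("<glyco_msa> ", length(x$labels), " rows x ", x$n_columns,
      " columns (source: ", x$source, ")\n", sep = "")
  invisible(x)
}

#' Character matrix view of an alignment
#' @param x A `glyco_msa`.
#' @return Matrix of single characters, rows named by taxon.
#' @export
msa_matrix <- function(x) {
  m <- do.call(rbind, lapply(x$seqs, split1))
  rownames(m) <- x$labels
  m
}

#' Remove gaps from alignment rows
#' @param x A `glyco_msa`.
#' @return Named character vector of ungapped sequences.
#' @export
degap <- function(x) {
  stats::setNames(gsub("-", "", x$seqs, fixed = TRUE), x$labels)
}

# gap fraction per column
msa_gap_fraction <- function(x) {
  m <- msa_matrix(x)
  colMeans(m == "-")
}
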