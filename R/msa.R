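# Progressive multiple alignment and the five-member parameter ensemble.
#
# One progressive aligner, run under distinct parameter sets (substitution
# matrix x gap costs x end-gap policy x guide-tree distance), stands in for
# the five external alignment programs of the original protocol: the
# ensemble's job is to generate plausible alternative alignments for
# consistency scoring, not to reproduce any particular tool. Externally
# produced alignments can be substituted via `member_files`.

#' Progressive multiple sequence alignment
#'
#' Builds a neighbor-joining guide tree from pairwise alignment identities
#' (or Kimura-corrected distances), then merges profiles in guide-tree
#' postorder with sum-of-pairs mean-profile scoring. No iterative
#' refinement is applied.
#'
#' @param seqs Named character vector of >= 2 unaligned sequences.
#' @param params An [align_params()].
#' @param guide_distance `"identity"` (d = 1 - identity) or `"corrected"`
#'   (Kimura protein / Jukes-Cantor nucleotide transform of the mismatch
#'   fraction).
#' @param guide Optional precomputed guide tree (`ape::phylo`, leaf labels
#'   equal to `names(seqs)`), e.g. shared across ensemble members.
#' @param source Label stored on the result.
#' @return A [msa()] object.
#' @export
progressive_msa <- function(seqs, params = align_params(),
                            guide_distance = c("identity", "corrected"),
                            guide = NULL, source = "progressive") {
  guide_distance <- match.arg(guide_distance)
  if (length(seqs) < 2L) stop("need at least two sequences to align")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique labels")
  if (length(seqs) == 2L) {
    pr <- pairwise_align(seqs[1], seqs[2], params)
    names(pr$alignment) <- names(seqs)
    return(msa(pr$alignment, source = source))
  }
  if (is.null(guide)) {
    D <- guide_distances(seqs, params, guide_distance)
    guide <- neighbor_joining(D)
  }
  if (!setequal(guide$tip.label, names(seqs)))
    stop("guide tree leaves do not match sequence labels")
  aln <- merge_by_tree(guide, seqs, params)
  aln$seqs <- aln$seqs[names(seqs)]
  aln$labels <- names(seqs)
  aln$source <- source
  aln
}

# pairwise guide distances from all-vs-all pairwise alignments
guide_distances <- function(seqs, params, guide_distance = "identity") {
  n <- length(seqs)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pr <- pairwise_align(seqs[i], seqs[j], params)
    p <- 1 - pr$identity
    d <- if (guide_distance == "identity") p
    else correct_distance(p, if (params$alphabet == "protein")
      "protein" else "nucleotide")
    if (!is.finite(d)) d <- NA_real_
    D[i, j] <- D[j, i] <- d
  }
  if (anyNA(D)) {
    mx <- max(D, na.rm = TRUE)
    D[is.na(D)] <- 2 * max(mx, 1)
  }
  D
}

# postorder profile merging along a (possibly multifurcating) guide tree
merge_by_tree <- function(tree, seqs, params) {
  nt <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  rec <- function(node) {
    if (node <= nt)
      return(msa(seqs[tree$tip.label[node]], source = "leaf"))
    kids <- children[[as.character(node)]]
    acc <- rec(kids[1])
    for (k in kids[-1]) acc <- merge_profiles(acc, rec(k), params)
    acc
  }
  rec(nt + 1L)
}

# frequency profile (alphabet x columns); gaps carry no mass
msa_profile <- function(x, params) {
  ab <- rownames(params$S)
  m <- msa_matrix(x)
  P <- matrix(0, nrow = length(ab), ncol = ncol(m),
              dimnames = list(ab, NULL))
  for (k in seq_along(ab)) P[k, ] <- colMeans(m == ab[k])
  known <- colSums(P) + colMeans(m == "-")
  if (any(known < 1 - 1e-9))
    stop("alignment contains symbols outside the scoring alphabet")
  P
}

# align two sub-alignments as profiles and expand rows along the path
merge_profiles <- function(a, b, params) {
  PA <- msa_profile(a, params)
  PB <- msa_profile(b, params)
  sc <- profile_scores(PA, PB, params$S)
  res <- .gotoh_align(sc, params$gap_open, params$gap_extend,
                      params$free_end_gaps)
  ma <- msa_matrix(a)
  mb <- msa_matrix(b)
  expand <- function(m, idx) {
    out <- matrix("-", nrow = nrow(m), ncol = length(idx))
    nz <- idx > 0L
    out[, nz] <- m[, idx[nz], drop = FALSE]
    rownames(out) <- rownames(m)
    out
  }
  rows <- rbind(expand(ma, res$a_idx), expand(mb, res$b_idx))
  msa(stats::setNames(apply(rows, 1, paste, collapse = ""), rownames(rows)),
      source = "merge")
}

# The five documented ensemble parameter sets. `reverse = TRUE` aligns the
# reversed sequences and mirrors the result back: dynamic-programming
# tie-breaking then places degenerate gaps at the opposite end of repeat
# regions, the kind of disagreement real aligner ensembles exhibit.
ensemble_parameter_sets <- function(alphabet) {
  if (alphabet == "protein") {
    list(
      list(matrix = "BLOSUM62", gap_open = -10, gap_extend = -0.1,
           free_end_gaps = TRUE,  guide = "identity",  reverse = FALSE),
      list(matrix = "BLOSUM62", gap_open = -10, gap_extend = -0.1,
           free_end_gaps = TRUE,  guide = "identity",  reverse = TRUE),
      list(matrix = "BLOSUM62", gap_open = -12, gap_extend = -2,
           free_end_gaps = FALSE, guide = "identity",  reverse = FALSE),
      list(matrix = "BLOSUM80", gap_open = -10, gap_extend = -0.1,
           free_end_gaps = TRUE,  guide = "identity",  reverse = FALSE),
      list(matrix = "BLOSUM80", gap_open = -12, gap_extend = -2,
           free_end_gaps = TRUE,  guide = "corrected", reverse = TRUE))
  } else {
    list(
      list(matrix = "NUC.5-4", gap_open = -15, gap_extend = -6.66,
           free_end_gaps = TRUE,  guide = "identity",  reverse = FALSE),
      list(matrix = "NUC.5-4", gap_open = -15, gap_extend = -6.66,
           free_end_gaps = TRUE,  guide = "identity",  reverse = TRUE),
      list(matrix = "NUC.5-4", gap_open = -10, gap_extend = -2,
           free_end_gaps = FALSE, guide = "identity",  reverse = FALSE),
      list(matrix = "NUC.5-4", gap_open = -20, gap_extend = -1,
           free_end_gaps = TRUE,  guide = "identity",  reverse = FALSE),
      list(matrix = "NUC.5-4", gap_open = -12, gap_extend = -4,
           free_end_gaps = TRUE,  guide = "corrected", reverse = TRUE))
  }
}

reverse_string <- function(s)
  vapply(s, function(x) paste(rev(split1(x)), collapse = ""), "",
         USE.NAMES = TRUE)

#' Build an alignment ensemble
#'
#' Runs the progressive aligner under `n_members` distinct, documented
#' parameter sets (two substitution matrices crossed with gap-cost,
#' end-gap-policy and guide-distance variants), or reads externally
#' produced member alignments from files.
#'
#' @param seqs Named character vector of >= 3 unaligned sequences.
#' @param n_members Number of ensemble members (2 to 5; default 5).
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @param member_files Optional character vector of aligned-FASTA files to
#'   use instead of the in-house aligner; each must cover the same label
#'   set and degap to the input sequences.
#' @return List of [msa()] objects.
#' @export
build_ensemble <- function(seqs, n_members = 5L,
                           alphabet = c("protein", "nucleotide"),
                           member_files = NULL) {
  alphabet <- match.arg(alphabet)
  if (length(seqs) < 3L) stop("an ensemble needs at least three sequences")
  if (!is.null(member_files)) {
    members <- lapply(seq_along(member_files), function(i) {
      rows <- read_fasta_raw(member_files[i])
      m <- msa(rows, source = basename(member_files[i]))
      validate_member(m, seqs)
      m
    })
    if (length(members) < 2L)
      stop("an ensemble of fewer than two members is meaningless")
    return(members)
  }
  if (n_members < 2L)
    stop("an ensemble of fewer than two members is meaningless")
  sets <- ensemble_parameter_sets(alphabet)
  if (n_members > length(sets))
    stop("at most ", length(sets), " built-in parameter sets are available")
  sets <- sets[seq_len(n_members)]
  base <- align_params(alphabet)
  id_D <- guide_distances(seqs, base, "identity")
  guides <- list(identity = neighbor_joining(id_D))
  lapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (is.null(guides[[s$guide]])) {
      D <- guide_distances(seqs, base, s$guide)
      guides[[s$guide]] <<- neighbor_joining(D)
    }
    p <- align_params(alphabet, matrix = s$matrix, gap_open = s$gap_open,
                      gap_extend = s$gap_extend,
                      free_end_gaps = s$free_end_gaps)
    src <- sprintf("set%d:%s/open%g/ext%g/%s/%s%s", i, s$matrix,
                   s$gap_open, s$gap_extend,
                   if (s$free_end_gaps) "freeends" else "endpen",
                   s$guide, if (s$reverse) "/rev" else "")
    if (s$reverse) {
      m <- progressive_msa(reverse_string(seqs), p,
                           guide = guides[[s$guide]], source = src)
      m$seqs <- reverse_string(m$seqs)
      m
    } else {
      progressive_msa(seqs, p, guide = guides[[s$guide]], source = src)
    }
  })
}

validate_member <- function(m, seqs) {
  if (!setequal(m$labels, names(seqs)))
    stop("ensemble member '", m$source, "' does not cover the input labels")
  dg <- degap(m)[names(seqs)]
  if (!identical(unname(dg), unname(toupper(seqs))))
    stop("ensemble member '", m$source,
         "' rows do not degap to the input sequences")
  invisible(m)
}
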