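# Independent oracles used to freeze expected values.

# Exhaustive global-alignment oracle: enumerates every monotone alignment
# path of a and b, scores it under the affine model (a gap run of length L
# costs open + L * ext; with free_ends the run touching either end of the
# alignment costs nothing), and returns the maximum score. Feasible for
# sequences up to ~6 residues.
enum_align_score <- function(a, b, S, open, ext, free_ends = TRUE) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  la <- length(ca)
  lb <- length(cb)
  best <- -Inf
  # moves: 1 = consume both, 2 = consume a (gap in b), 3 = consume b
  rec <- function(i, j, cols) {
    if (i == la && j == lb) {
      sc <- score_alignment(cols, ca, cb, S, open, ext, free_ends)
      if (sc > best) best <<- sc
      return(invisible())
    }
    if (i < la && j < lb) rec(i + 1L, j + 1L, c(cols, 1L))
    if (i < la) rec(i + 1L, j, c(cols, 2L))
    if (j < lb) rec(i, j + 1L, c(cols, 3L))
    invisible()
  }
  rec(0L, 0L, integer(0))
  best
}

score_alignment <- function(cols, ca, cb, S, open, ext, free_ends) {
  n <- length(cols)
  # identify maximal gap runs (same move repeated)
  runs <- rle(cols)
  sc <- 0
  i <- 0L  # consumed of a
  j <- 0L  # consumed of b
  pos <- 0L
  nrun <- length(runs$values)
  for (r in seq_len(nrun)) {
    v <- runs$values[r]
    len <- runs$lengths[r]
    if (v == 1L) {
      for (k in seq_len(len))
        sc <- sc + S[ca[i + k], cb[j + k]]
      i <- i + len
      j <- j + len
    } else {
      is_lead <- pos == 0L
      is_trail <- pos + len == n
      charged <- !(free_ends && (is_lead || is_trail))
      if (charged) sc <- sc + open + len * ext
      if (v == 2L) i <- i + len else j <- j + len
    }
    pos <- pos + len
  }
  sc
}

# Sum-of-pairs score of a set of gapped rows: affine score of every induced
# pairwise alignment (columns gapped in both rows dropped), end gaps free.
sp_score <- function(rows, S, open, ext) {
  m <- do.call(rbind, strsplit(rows, ""))
  total <- 0
  for (a in seq_len(nrow(m) - 1L)) for (b in (a + 1L):nrow(m)) {
    keep <- !(m[a, ] == "-" & m[b, ] == "-")
    ra <- m[a, keep]
    rb <- m[b, keep]
    cols <- ifelse(ra != "-" & rb != "-", 1L, ifelse(rb == "-", 2L, 3L))
    total <- total + score_alignment(
      cols, ra[ra != "-"], rb[rb != "-"], S, open, ext, TRUE)
  }
  total
}

# Exhaustive three-sequence alignment: maximum sum-of-pairs score over all
# monotone 3D paths. Feasible for lengths <= 4.
enum_msa3_best_sp <- function(s1, s2, s3, S, open, ext) {
  cs <- lapply(c(s1, s2, s3), function(s) strsplit(s, "")[[1]])
  lens <- lengths(cs)
  moves <- as.matrix(expand.grid(0:1, 0:1, 0:1))[-1, ]
  best <- -Inf
  rec <- function(idx, rows) {
    if (all(idx == lens)) {
      sc <- sp_score(vapply(rows, paste, "", collapse = ""), S, open, ext)
      if (sc > best) best <<- sc
      return(invisible())
    }
    for (mv in seq_len(nrow(moves))) {
      d <- moves[mv, ]
      if (any(idx + d > lens)) next
      nr <- rows
      for (q in 1:3)
        nr[[q]] <- c(nr[[q]], if (d[q] == 1) cs[[q]][idx[q] + 1L] else "-")
      rec(idx + d, nr)
    }
    invisible()
  }
  rec(c(0L, 0L, 0L), list(character(0), character(0), character(0)))
  best
}

# random nucleotide / protein sequences
rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
rand_aa <- function(n) paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV",
                                             "")[[1]], n, TRUE),
                             collapse = "")
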