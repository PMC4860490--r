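# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All stochastic operations in the package go
# through this so a single integer seed pins every result.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Reverse complement of a nucleotide sequence
#'
#' @param seq Single character string over `A`, `C`, `G`, `T`, `N`.
#' @return The reverse complement, upper case.
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(toupper(seq), "")[[1]]),
                                 collapse = ""))
}

# Validate a nucleotide sequence: {A,C,G,T,N} only (case-insensitive),
# returned upper case. Other IUPAC ambiguity codes are rejected outright so
# downstream GC and alignment arithmetic stays unambiguous.
check_nt <- function(seq, what = "sequence") {
  seq <- toupper(seq)
  bad <- gsub("[ACGTN]", "", seq)
  if (any(nchar(bad) > 0L)) {
    ch <- unique(strsplit(paste(bad, collapse = ""), "")[[1]])
    stop(what, " contains characters outside {A,C,G,T,N}: ",
         paste(ch, collapse = ", "))
  }
  seq
}

split1 <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# round-half-up to integer (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)
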