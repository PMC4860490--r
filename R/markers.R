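# The marker scheme: the nine canonical glycolysis enzymes of
# Bifidobacterium (6-phosphofructokinase, pathway step 3, is absent in the
# genus, so index 3 never appears) plus the 16S rRNA gene used for the
# reference phylogeny.

#' The glycolysis marker scheme
#'
#' Nine protein-coding markers ordered by their position in the glycolysis
#' pathway, plus the 16S rRNA gene (`rrs16S`, untranslated).
#'
#' @param include_16s Append the `rrs16S` row.
#' @return Data frame with columns `symbol`, `ec_number`, `pathway_index`,
#'   `enzyme`.
#' @export
glycolysis_markers <- function(include_16s = FALSE) {
  m <- data.frame(
    symbol = c("pgm", "pgi", "fba", "tpi", "gap", "pgk", "gpm", "eno", "pyk"),
    ec_number = c("5.4.2.2", "5.3.1.9", "4.1.2.13", "5.3.1.1", "1.2.1.12",
                  "2.7.2.3", "5.4.2.11", "4.2.1.11", "2.7.1.40"),
    pathway_index = c(1L, 2L, 4L, 5L, 6L, 7L, 8L, 9L, 10L),
    enzyme = c("phosphoglucomutase", "glucose-6-phosphate isomerase",
               "fructose bisphosphate aldolase", "triose phosphate isomerase",
               "glyceraldehyde 3-phosphate dehydrogenase",
               "phosphoglycerate kinase", "phosphoglycerate mutase",
               "enolase", "pyruvate kinase"),
    stringsAsFactors = FALSE)
  if (include_16s)
    m <- rbind(m, data.frame(symbol = "rrs16S", ec_number = "",
                             pathway_index = NA_integer_,
                             enzyme = "16S ribosomal RNA"))
  m
}

# ---- translation (bacterial table 11) -----------------------------------

GENETIC_CODE_11 <- local({
  b <- c("T", "C", "A", "G")
  # 64 codons in TCAG order by first, second, third base
  codons <- character(64)
  k <- 0L
  for (b1 in b) for (b2 in b) for (b3 in b) {
    k <- k + 1L
    codons[k] <- paste0(b1, b2, b3)
  }
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",  # TTT..TGG
    "LLLLPPPPHHQQRRRR",  # CTT..CGG
    "IIIMTTTTNNKKSSRR",  # ATT..AGG
    "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aas, codons)
})

#' Translate a CDS under the bacterial genetic code
#'
#' A terminal stop codon is stripped; the alternative initiation codons
#' `GTG` and `TTG` at position 0 translate as `M`. An internal stop is a
#' pseudogene-like defect and raises an error.
#'
#' @param nt_seq Coding-strand sequence over `A`,`C`,`G`,`T`, length a
#'   multiple of 3.
#' @param genetic_code NCBI table id; only 11 is supported.
#' @return The amino-acid sequence.
#' @export
translate_cds <- function(nt_seq, genetic_code = 11L) {
  if (as.integer(genetic_code) != 11L)
    stop("only genetic code table 11 is supported")
  nt_seq <- toupper(nt_seq)
  if (grepl("[^ACGT]", nt_seq))
    stop("CDS contains characters outside {A,C,G,T}")
  n <- nchar(nt_seq)
  if (n == 0L || n %% 3L != 0L)
    stop("frame error: CDS length ", n, " is not a positive multiple of 3")
  codons <- substring(nt_seq, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- GENETIC_CODE_11[codons]
  if (aa[length(aa)] == "*") aa <- aa[-length(aa)]
  if (any(aa == "*"))
    stop("pseudogene-like CDS: internal stop codon at codon ",
         which(aa == "*")[1])
  if (length(aa) && codons[1] %in% c("GTG", "TTG")) aa[1] <- "M"
  paste(aa, collapse = "")
}

# ---- marker reference database ------------------------------------------

#' Read or write a marker reference database
#'
#' Multi-FASTA with headers `>symbol|species|type` where `type` is `nt` or
#' `aa`; holds the reference sequences (typically from the four reference
#' species) for the nine glycolysis genes and the 16S rRNA gene.
#'
#' @param path FASTA file.
#' @return `read_marker_db`: data frame with columns `symbol`, `species`,
#'   `type`, `seq`.
#' @export
read_marker_db <- function(path) {
  seqs <- read_fasta_raw(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad))
    stop("marker database headers must be 'symbol|species|type'; offending: ",
         names(seqs)[bad][1])
  data.frame(symbol = vapply(parts, `[`, "", 1L),
             species = vapply(parts, `[`, "", 2L),
             type = vapply(parts, `[`, "", 3L),
             seq = unname(seqs), stringsAsFactors = FALSE)
}

#' @rdname read_marker_db
#' @param db Data frame as returned by `read_marker_db`.
#' @export
write_marker_db <- function(db, path) {
  seqs <- stats::setNames(db$seq, paste(db$symbol, db$species, db$type,
                                        sep = "|"))
  write_fasta(seqs, path)
}

# plain FASTA reader that tolerates any residue letters and gaps
read_fasta_raw <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", path)
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    if (hdr[i] + 1L > ends[i]) return("")
    toupper(gsub("\\s", "", paste(lines[(hdr[i] + 1L):ends[i]],
                                  collapse = "")))
  }, "")
  names(seqs) <- sub("^>", "", trimws(lines[hdr]))
  seqs
}
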