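# Genome I/O: annotated assemblies as GenBank flat files or plain FASTA.
#
# Internally all feature coordinates are 0-based, half-open; GenBank files
# use the on-disk convention of 1-based inclusive spans. No installed R
# package parses GenBank flat files with their feature table, so a minimal
# reader/writer for the LOCUS/FEATURES/ORIGIN dialect lives here.

#' Construct a genome record
#'
#' An annotated assembly: contig sequences plus CDS features. Coordinates are
#' 0-based half-open on the forward strand; minus-strand features are
#' extracted as the reverse complement of the spanned forward-strand slice.
#'
#' @param genome_id Accession-like identifier.
#' @param label Naming-convention label, `genus-initial_species[_subsp]`
#'   (e.g. `B_longum_i`).
#' @param contigs Named character vector of contig sequences
#'   (alphabet `A`,`C`,`G`,`T`,`N`; stored upper case).
#' @param cds_features Data frame with columns `contig_id`, `start`, `end`,
#'   `strand` (`+`/`-`), `locus_tag`, `product`, and an optional list column
#'   `segments` holding exon spans for compound (`join`) locations.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(genome_id, label, contigs,
                          cds_features = empty_cds_table()) {
  stopifnot(is.character(contigs), length(contigs) >= 1L,
            !is.null(names(contigs)))
  contigs <- vapply(contigs, check_nt, "", what = "contig", USE.NAMES = TRUE)
  # naming convention: genus-initial_species[_subsp] (B_longum_i); plain
  # alphanumeric identifiers (synthetic cohorts) are also accepted
  if (!grepl("^[A-Za-z][A-Za-z0-9]*(_[A-Za-z0-9]+)*$", label))
    warning("label '", label,
            "' does not follow the genus-initial_species naming convention")
  cds_features <- validate_cds(cds_features, contigs)
  structure(list(genome_id = genome_id, label = label, contigs = contigs,
                 cds_features = cds_features),
            class = "genome_record")
}

empty_cds_table <- function() {
  data.frame(contig_id = character(), start = integer(), end = integer(),
             strand = character(), locus_tag = character(),
             product = character(), stringsAsFactors = FALSE)
}

validate_cds <- function(cds, contigs) {
  if (nrow(cds) == 0L) return(cds)
  if (!all(cds$contig_id %in% names(contigs)))
    stop("CDS feature references unknown contig: ",
         paste(setdiff(cds$contig_id, names(contigs)), collapse = ", "))
  len <- nchar(contigs)[cds$contig_id]
  ok <- cds$start >= 0L & cds$start < cds$end & cds$end <= len
  if (!all(ok))
    stop("CDS coordinates outside contig bounds for locus_tag(s): ",
         paste(cds$locus_tag[!ok], collapse = ", "))
  if (!all(cds$strand %in% c("+", "-")))
    stop("CDS strand must be '+' or '-'")
  cds
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record>", x$genome_id, " (", x$label, ")\n", sep = "")
  cat("  contigs: ", length(x$contigs), " (",
      format(sum(nchar(x$contigs)), big.mark = ","), " bp)\n", sep = "")
  cat("  CDS features:", nrow(x$cds_features), "\n")
  invisible(x)
}

#' Extract the nucleotide sequence of a CDS feature
#'
#' Compound (`join`) locations concatenate their exon spans in feature order;
#' minus-strand features return the reverse complement of that concatenation.
#'
#' @param genome A `genome_record`.
#' @param i Row index into `genome$cds_features`.
#' @return Coding-strand nucleotide sequence.
#' @export
cds_sequence <- function(genome, i) {
  f <- genome$cds_features[i, , drop = FALSE]
  contig <- genome$contigs[[f$contig_id]]
  segs <- if (!is.null(genome$cds_features$segments))
    genome$cds_features$segments[[i]] else NULL
  if (is.null(segs)) segs <- cbind(f$start, f$end)
  s <- paste(vapply(seq_len(nrow(segs)), function(k)
    substr(contig, segs[k, 1] + 1L, segs[k, 2]), ""), collapse = "")
  if (f$strand == "-") reverse_complement(s) else s
}

#' Read an annotated genome from GenBank or FASTA
#'
#' The dialect is auto-detected (a leading `LOCUS` keyword means GenBank).
#' FASTA input yields a record with contigs and an empty feature table.
#'
#' @param path File path.
#' @param genome_id,label Overrides; default to values parsed from the file
#'   (FASTA: the file stem).
#' @return A [genome_record()].
#' @export
read_genome <- function(path, genome_id = NULL, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^LOCUS", first)) {
    rec <- read_genbank(path)
  } else if (grepl("^>", first)) {
    dna <- ape::read.FASTA(path)
    contigs <- toupper(vapply(as.character(dna), paste, "", collapse = ""))
    names(contigs) <- sub("\\s.*$", "", names(dna))
    stem <- sub("\\.[^.]*$", "", basename(path))
    rec <- list(genome_id = stem, contigs = contigs,
                cds_features = empty_cds_table())
  } else stop("cannot parse ", path,
              ": expected GenBank (LOCUS) or FASTA (>) at line 1")
  gid <- genome_id %||% rec$genome_id
  genome_record(gid, label %||% gid, rec$contigs, rec$cds_features)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- GenBank flat-file parsing ------------------------------------------

read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^//", lines)
  if (length(ends) == 0L) ends <- length(lines)
  starts <- c(1L, head(ends, -1L) + 1L)
  contigs <- character()
  cds <- list()
  segs <- list()
  gid <- NULL
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:ends[r]]
    block <- block[nzchar(trimws(block))]
    if (length(block) == 0L) next
    locus <- grep("^LOCUS", block, value = TRUE)
    if (length(locus) == 0L)
      stop("GenBank record ", r, " in ", path, " lacks a LOCUS line")
    contig_id <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1]
    if (is.null(gid)) {
      acc <- grep("^ACCESSION", block, value = TRUE)
      gid <- if (length(acc))
        strsplit(trimws(sub("^ACCESSION", "", acc[1])), "\\s+")[[1]][1]
      else contig_id
    }
    ori <- grep("^ORIGIN", block)
    if (length(ori) == 0L)
      stop("GenBank record for ", contig_id, " has no ORIGIN section")
    seqlines <- block[(ori[1] + 1L):length(block)]
    seq <- toupper(gsub("[0-9 /]", "", paste(seqlines, collapse = "")))
    contigs[contig_id] <- seq
    feat <- grep("^FEATURES", block)
    if (length(feat)) {
      fl <- block[(feat[1] + 1L):(ori[1] - 1L)]
      parsed <- parse_feature_table(fl, contig_id, path)
      cds <- c(cds, parsed$rows)
      segs <- c(segs, parsed$segments)
    }
  }
  tab <- if (length(cds)) do.call(rbind, cds) else empty_cds_table()
  if (length(segs)) tab$segments <- segs
  list(genome_id = gid, contigs = contigs, cds_features = tab)
}

parse_feature_table <- function(fl, contig_id, path) {
  # feature keys start at column 6; qualifiers/continuations at column 22
  key_idx <- grep("^ {4,5}\\S", fl)
  rows <- list()
  segments <- list()
  for (k in seq_along(key_idx)) {
    i <- key_idx[k]
    end <- if (k < length(key_idx)) key_idx[k + 1L] - 1L else length(fl)
    key <- strsplit(trimws(fl[i]), "\\s+")[[1]][1]
    if (key != "CDS") next
    body <- trimws(fl[i:end])
    body[1] <- sub("^CDS\\s+", "", body[1])
    # location may wrap over lines until the first qualifier
    qual_at <- grep("^/", body)
    loc_end <- if (length(qual_at)) qual_at[1] - 1L else length(body)
    loc <- paste(body[seq_len(loc_end)], collapse = "")
    pl <- parse_location(loc, path)
    quals <- body[grep("^/", body)]
    getq <- function(name) {
      hit <- grep(paste0("^/", name, "="), quals, value = TRUE)
      if (!length(hit)) return("")
      gsub("\"", "", sub(paste0("^/", name, "="), "", hit[1]))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      contig_id = contig_id,
      start = min(pl$segments[, 1]), end = max(pl$segments[, 2]),
      strand = pl$strand, locus_tag = getq("locus_tag"),
      product = getq("product"), stringsAsFactors = FALSE)
    segments[[length(segments) + 1L]] <- pl$segments
  }
  list(rows = rows, segments = segments)
}

# "a..b", "complement(a..b)", "join(a..b,c..d)", "complement(join(...))"
parse_location <- function(loc, path) {
  strand <- "+"
  loc <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  segs <- t(vapply(parts, function(p) {
    m <- regmatches(p, regexec("^<?([0-9]+)\\.\\.>?([0-9]+)$", p))[[1]]
    if (length(m) != 3L)
      stop("cannot parse CDS location '", p, "' in ", path)
    c(as.integer(m[2]) - 1L, as.integer(m[3]))  # to 0-based half-open
  }, integer(2)))
  dimnames(segs) <- NULL
  if (any(segs[, 1] >= segs[, 2]))
    stop("degenerate CDS span in location '", loc, "'")
  list(strand = strand, segments = segs)
}

#' Write a genome record as a GenBank flat file
#'
#' Inverse of [read_genome()] for the GenBank dialect: coordinates are
#' emitted 1-based inclusive, so reading the file back reproduces the record.
#'
#' @param genome A `genome_record`.
#' @param path Output file.
#' @export
write_genbank <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cid in names(genome$contigs)) {
    seq <- genome$contigs[[cid]]
    writeLines(sprintf("LOCUS       %s %d bp    DNA     linear   BCT", cid,
                       nchar(seq)), con)
    writeLines(sprintf("DEFINITION  %s %s.", genome$label, cid), con)
    writeLines(sprintf("ACCESSION   %s", genome$genome_id), con)
    writeLines("FEATURES             Location/Qualifiers", con)
    writeLines(sprintf("     source          1..%d", nchar(seq)), con)
    cds <- genome$cds_features
    idx <- which(cds$contig_id == cid)
    for (i in idx) {
      segs <- if (!is.null(cds$segments)) cds$segments[[i]] else
        cbind(cds$start[i], cds$end[i])
      spans <- paste(sprintf("%d..%d", segs[, 1] + 1L, segs[, 2]),
                     collapse = ",")
      if (nrow(segs) > 1L) spans <- sprintf("join(%s)", spans)
      if (cds$strand[i] == "-") spans <- sprintf("complement(%s)", spans)
      writeLines(sprintf("     CDS             %s", spans), con)
      writeLines(sprintf("                     /locus_tag=\"%s\"",
                         cds$locus_tag[i]), con)
      if (nzchar(cds$product[i]))
        writeLines(sprintf("                     /product=\"%s\"",
                           cds$product[i]), con)
    }
    writeLines("ORIGIN", con)
    pos <- seq(1L, nchar(seq), by = 60L)
    for (p in pos) {
      chunk <- substr(seq, p, min(p + 59L, nchar(seq)))
      tens <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
      writeLines(sprintf("%9d %s", p, tolower(paste(tens, collapse = " "))),
                 con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

# FASTA convenience wrappers (labels -> sequences as character vectors)
read_fasta <- function(path, type = c("nt", "aa")) {
  type <- match.arg(type)
  x <- ape::read.FASTA(path, type = if (type == "aa") "AA" else "DNA")
  out <- toupper(vapply(as.character(x), paste, "", collapse = ""))
  names(out) <- names(x)
  out
}

write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    writeLines(substring(s, seq(1, nchar(s), width),
                         pmin(seq(width, nchar(s) + width - 1, width),
                              nchar(s))), con)
  }
  invisible(path)
}
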