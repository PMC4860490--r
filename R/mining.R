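# Marker mining: locate the glycolysis gene orthologs among a genome's
# annotated CDS features by global nucleotide alignment against the marker
# reference database, extract the 16S rRNA gene by seed-and-extend search,
# and concatenate the translated markers in pathway order.
#
# "Similarity" is operationalized as global-alignment nucleotide identity
# (matches / alignment length, gap columns included), the conservative
# reading of the 40% mining cut-off.

nt_mining_params <- function() align_params("nucleotide")

#' Locate a marker ortholog among a genome's CDS features
#'
#' Every CDS is globally aligned against each reference sequence of the
#' marker; CDSs whose best identity reaches `min_similarity` qualify, and
#' the qualifying CDS with the highest alignment score wins. Ties resolve
#' to the longer CDS, then the lexicographically smaller locus tag.
#'
#' @param genome A [genome_record()] with at least one CDS feature.
#' @param symbol Marker symbol (e.g. `"pgm"`).
#' @param db Marker reference database ([read_marker_db()] layout); only
#'   `type == "nt"` rows for `symbol` are used.
#' @param min_similarity Identity cut-off (default 0.40).
#' @param genetic_code Translation table (11).
#' @return A `marker_hit` list (`genome_id`, `symbol`, `nt_seq`, `aa_seq`,
#'   `similarity`, `score`, `feature` row index) or `NULL` when no CDS
#'   qualifies.
#' @export
find_marker <- function(genome, symbol, db, min_similarity = 0.40,
                        genetic_code = 11L) {
  if (nrow(genome$cds_features) == 0L)
    stop("unannotated genome: ", genome$genome_id, " has no CDS features")
  refs <- db$seq[db$symbol == symbol & db$type == "nt"]
  if (!length(refs)) stop("marker ", symbol, " has no nt reference in the db")
  params <- nt_mining_params()
  best <- NULL
  for (i in seq_len(nrow(genome$cds_features))) {
    s <- cds_sequence(genome, i)
    cand <- best_reference_alignment(s, refs, params, min_similarity)
    if (is.null(cand)) next
    cand$feature <- i
    cand$len <- nchar(s)
    cand$locus_tag <- genome$cds_features$locus_tag[i]
    if (is.null(best) || better_hit(cand, best)) best <- cand
  }
  if (is.null(best)) return(NULL)
  aa <- translate_cds(best$nt_seq, genetic_code)
  structure(list(genome_id = genome$genome_id, symbol = symbol,
                 nt_seq = best$nt_seq, aa_seq = aa,
                 similarity = best$similarity, score = best$score,
                 feature = best$feature),
            class = "marker_hit")
}

# score a sequence against a reference set; NULL unless the best identity
# clears the cut-off. Length-ratio prefilter: identity can never exceed
# min(la,lb)/max(la,lb), so shorter pairs are skipped without aligning.
best_reference_alignment <- function(s, refs, params, min_similarity) {
  best <- NULL
  for (r in refs) {
    ratio <- min(nchar(s), nchar(r)) / max(nchar(s), nchar(r))
    if (ratio < min_similarity) next
    pr <- pairwise_align(s, r, params)
    if (is.null(best) || pr$score > best$score)
      best <- list(nt_seq = s, similarity = pr$identity, score = pr$score)
  }
  if (is.null(best) || best$similarity < min_similarity) return(NULL)
  best
}

better_hit <- function(a, b) {
  if (a$score != b$score) return(a$score > b$score)
  if (a$len != b$len) return(a$len > b$len)
  a$locus_tag < b$locus_tag
}

#' Mine one genome for all protein markers
#'
#' @param genome A [genome_record()].
#' @param db Marker reference database.
#' @param config A [pipeline_config()].
#' @param strict Fail if any of the nine markers is missing (default); when
#'   `FALSE` missing markers are reported as absent.
#' @return List with `hits` (named list of `marker_hit`) and `report`
#'   (one row per marker: locus tag, coordinates, strand, similarity,
#'   amino-acid length).
#' @export
mine_genome <- function(genome, db, config = pipeline_config(),
                        strict = TRUE) {
  defs <- glycolysis_markers()
  hits <- lapply(defs$symbol, function(sym)
    find_marker(genome, sym, db, config$min_similarity,
                config$genetic_code))
  names(hits) <- defs$symbol
  missing <- defs$symbol[vapply(hits, is.null, TRUE)]
  if (strict && length(missing))
    stop("genome ", genome$genome_id, " is missing marker(s): ",
         paste(missing, collapse = ", "))
  report <- do.call(rbind, lapply(defs$symbol, function(sym) {
    h <- hits[[sym]]
    if (is.null(h))
      return(data.frame(genome_id = genome$genome_id, symbol = sym,
                        locus_tag = NA, start = NA, end = NA, strand = NA,
                        similarity = NA, aa_length = NA))
    f <- genome$cds_features[h$feature, ]
    data.frame(genome_id = genome$genome_id, symbol = sym,
               locus_tag = f$locus_tag, start = f$start, end = f$end,
               strand = f$strand, similarity = h$similarity,
               aa_length = nchar(h$aa_seq))
  }))
  list(hits = Filter(Negate(is.null), hits), report = report)
}

#' Concatenate one genome's marker proteins in pathway order
#'
#' @param hits List of nine `marker_hit` objects (one per protein marker,
#'   any order).
#' @return List with `seq` (the concatenated amino-acid sequence) and
#'   `partitions` (data frame `symbol`, `start`, `end`; 1-based inclusive
#'   coordinates in the concatenation, ordered by pathway index).
#' @export
concatenate_markers <- function(hits) {
  defs <- glycolysis_markers()
  syms <- vapply(hits, `[[`, "", "symbol")
  if (anyDuplicated(syms))
    stop("duplicate marker hit(s): ",
         paste(unique(syms[duplicated(syms)]), collapse = ", "))
  missing <- setdiff(defs$symbol, syms)
  if (length(missing))
    stop("missing marker(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(syms, defs$symbol)
  if (length(extra))
    stop("unknown marker symbol(s): ", paste(extra, collapse = ", "))
  ord <- defs$symbol[order(defs$pathway_index)]
  aa <- vapply(ord, function(s) hits[[which(syms == s)]]$aa_seq, "")
  len <- nchar(aa)
  end <- cumsum(len)
  start <- c(1L, head(end, -1L) + 1L)
  list(seq = paste(aa, collapse = ""),
       partitions = data.frame(symbol = ord, start = start, end = end,
                               row.names = NULL))
}

# ---- 16S extraction ------------------------------------------------------

#' Extract the 16S rRNA gene by similarity search
#'
#' Seed-and-extend: exact reference k-mers anchor candidate windows on both
#' strands, each window is globally aligned (free end gaps) against the
#' reference set, and the best-scoring locus above the identity cut-off is
#' returned untranslated.
#'
#' @param genome A [genome_record()].
#' @param db Marker database holding `rrs16S` nt references.
#' @param min_similarity Identity cut-off (default 0.40).
#' @param k Seed length (default 15).
#' @return A `marker_hit`-style list with `nt_seq`, `similarity`, `score`,
#'   `contig_id`, `start`, `end`, `strand` (0-based half-open on the
#'   forward strand), or `NULL` when no locus qualifies.
#' @export
extract_16s <- function(genome, db, min_similarity = 0.40, k = 15L) {
  refs <- db$seq[db$symbol == "rrs16S" & db$type == "nt"]
  if (!length(refs)) stop("no rrs16S reference in the marker database")
  params <- nt_mining_params()
  best <- NULL
  for (cid in names(genome$contigs)) {
    contig <- genome$contigs[[cid]]
    for (strand in c("+", "-")) {
      s <- if (strand == "+") contig else reverse_complement(contig)
      for (r in refs) {
        for (w in candidate_windows(s, r, k)) {
          sub <- substr(s, w[1], w[2])
          pr <- pairwise_align(sub, r, params)
          # trim the window to the aligned core (reference coverage)
          core <- aligned_core(pr$alignment)
          if (is.null(core)) next
          st <- w[1] + core[1] - 1L
          en <- w[1] + core[2] - 1L
          seq <- substr(s, st, en)
          pr2 <- pairwise_align(seq, r, params)
          cand <- list(nt_seq = seq, similarity = pr2$identity,
                       score = pr2$score, contig_id = cid, strand = strand,
                       start = if (strand == "+") st - 1L
                               else nchar(s) - en,
                       end = if (strand == "+") en else nchar(s) - st + 1L)
          if (cand$similarity >= min_similarity &&
              (is.null(best) || cand$score > best$score)) best <- cand
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  structure(c(list(genome_id = genome$genome_id, symbol = "rrs16S"),
              best), class = "marker_hit")
}

# windows of `s` anchored by exact matches of reference k-mer seeds
candidate_windows <- function(s, ref, k, stride = 40L, margin = 150L) {
  starts <- seq(1L, max(1L, nchar(ref) - k + 1L), by = stride)
  hits <- list()
  for (p in starts) {
    seed <- substr(ref, p, p + k - 1L)
    if (nchar(seed) < k) next
    m <- gregexpr(seed, s, fixed = TRUE)[[1]]
    if (m[1] == -1L) next
    for (pos in m) hits[[length(hits) + 1L]] <- c(diag = pos - p, pos = pos)
  }
  if (!length(hits)) return(list())
  h <- do.call(rbind, hits)
  # cluster seed hits whose implied reference offsets are near-collinear
  ord <- order(h[, "diag"])
  h <- h[ord, , drop = FALSE]
  grp <- cumsum(c(1, diff(h[, "diag"]) > 100))
  lapply(split(seq_len(nrow(h)), grp), function(idx) {
    d <- h[idx, "diag"]
    w1 <- max(1L, min(d) + 1L - margin)
    w2 <- min(nchar(s), max(d) + nchar(ref) + margin)
    c(w1, w2)
  })
}

# 1-based span of window positions aligned to (covered by) the reference
aligned_core <- function(alignment) {
  a <- split1(alignment[1])  # window row
  b <- split1(alignment[2])  # reference row
  apos <- cumsum(a != "-")
  covered <- which(b != "-" & a != "-")
  if (!length(covered)) return(NULL)
  c(apos[covered[1]], apos[covered[length(covered)]])
}

#' Mine a cohort of genomes
#'
#' Runs [mine_genome()] and [extract_16s()] over every genome, builds the
#' per-genome concatenated protein set, and assembles tidy reports.
#'
#' @param genomes List of [genome_record()] objects.
#' @param db Marker reference database.
#' @param config A [pipeline_config()].
#' @return List with `concat` (named vector of concatenated proteins, one
#'   per genome label), `partitions` (per-genome partition tables),
#'   `seqs_16s` (named vector of 16S sequences; absent loci dropped with a
#'   warning), `report` (mining table over all genomes), `hits`.
#' @export
mine_cohort <- function(genomes, db, config = pipeline_config()) {
  labels <- vapply(genomes, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("duplicate genome labels in cohort")
  mined <- lapply(genomes, mine_genome, db = db, config = config)
  concat <- lapply(mined, function(m) concatenate_markers(m$hits))
  s16 <- lapply(genomes, extract_16s, db = db,
                min_similarity = config$min_similarity)
  miss16 <- labels[vapply(s16, is.null, TRUE)]
  if (length(miss16))
    warning("no 16S rRNA locus found in: ", paste(miss16, collapse = ", "))
  have16 <- !vapply(s16, is.null, TRUE)
  list(concat = stats::setNames(vapply(concat, `[[`, "", "seq"), labels),
       partitions = stats::setNames(lapply(concat, `[[`, "partitions"),
                                    labels),
       seqs_16s = stats::setNames(
         vapply(s16[have16], `[[`, "", "nt_seq"), labels[have16]),
       hits_16s = stats::setNames(s16, labels),
       report = do.call(rbind, lapply(mined, `[[`, "report")),
       hits = stats::setNames(lapply(mined, `[[`, "hits"), labels))
}
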