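# GC-content analysis: per-sequence GC fractions, the genus's low/medium/
# high GC tri-partition, per-gene vs genome-wide GC trends, and the
# notched-boxplot median comparison.

#' GC fraction of a nucleotide sequence
#'
#' `(G + C) / (A + C + G + T)`; `N` is excluded from both numerator and
#' denominator.
#'
#' @param seq Character string over `A`,`C`,`G`,`T`,`N` (case-insensitive).
#' @return Fraction in `[0, 1]`.
#' @export
gc_fraction <- function(seq) {
  seq <- check_nt(seq, "sequence")
  counts <- table(factor(split1(seq), levels = c("A", "C", "G", "T", "N")))
  denom <- sum(counts[c("A", "C", "G", "T")])
  if (denom == 0L) stop("sequence has no unambiguous bases")
  unname((counts[["G"]] + counts[["C"]]) / denom)
}

#' The low/medium/high GC class scheme
#'
#' Bands spanning the genus's observed range: low `[0.52, 0.567)`, medium
#' `[0.567, 0.613)`, high `[0.613, 0.66]`. Intervals are half-open on the
#' right except the last.
#'
#' @return Object of class `gc_scheme` with the band boundaries.
#' @export
gc_scheme <- function() {
  structure(list(breaks = c(0.52, 0.567, 0.613, 0.66),
                 classes = c("low", "medium", "high")),
            class = "gc_scheme")
}

#' Classify a GC value into the low/medium/high partition
#'
#' Values below the scheme's range clamp to `low` and values above it to
#' `high`, each with a warning.
#'
#' @param value GC fraction in `[0, 1]`.
#' @param scheme A [gc_scheme()].
#' @return `"low"`, `"medium"` or `"high"`.
#' @export
classify_gc <- function(value, scheme = gc_scheme()) {
  stopifnot(value >= 0, value <= 1)
  b <- scheme$breaks
  if (value < b[1]) {
    warning("GC value ", value, " below the scheme range; clamped to low")
    return("low")
  }
  if (value > b[4]) {
    warning("GC value ", value, " above the scheme range; clamped to high")
    return("high")
  }
  if (value < b[2]) "low" else if (value < b[3]) "medium" else "high"
}

#' Per-genome GC profile
#'
#' Genome-wide GC over all contigs plus per-marker GC on each mined marker
#' CDS (and the 16S locus), with the genome's GC class.
#'
#' @param genome A [genome_record()].
#' @param hits Named list of `marker_hit` objects for this genome (the nine
#'   proteins; include the 16S hit under `rrs16S` if available).
#' @param scheme A [gc_scheme()].
#' @return List of class `gc_profile`: `genome_id`, `label`, `total_gc`,
#'   `per_marker_gc` (named numeric), `gc_class`.
#' @export
gc_profile <- function(genome, hits, scheme = gc_scheme()) {
  total <- gc_fraction(paste(genome$contigs, collapse = ""))
  per <- vapply(hits, function(h) gc_fraction(h$nt_seq), 0)
  structure(list(genome_id = genome$genome_id, label = genome$label,
                 total_gc = total, per_marker_gc = per,
                 gc_class = classify_gc(total, scheme)),
            class = "gc_profile")
}

#' Per-marker GC trend against genome-wide GC
#'
#' For each marker, counts the genomes whose marker GC lies below their
#' genome-wide GC. The report is ordered by pathway index with the 16S gene
#' last. Profiles missing a marker are excluded from that marker's counts
#' with a warning.
#'
#' @param profiles List of [gc_profile()] objects.
#' @return Data frame `symbol`, `n_below`, `n_above_or_equal`,
#'   `fraction_below`.
#' @export
gene_vs_genome_trend <- function(profiles) {
  if (!length(profiles)) stop("no GC profiles supplied")
  defs <- glycolysis_markers(include_16s = TRUE)
  syms <- defs$symbol[order(defs$pathway_index, na.last = TRUE)]
  rows <- lapply(syms, function(sym) {
    have <- vapply(profiles, function(p) sym %in% names(p$per_marker_gc),
                   TRUE)
    if (!all(have))
      warning(sum(!have), " profile(s) lack marker ", sym,
              "; excluded from its counts")
    below <- vapply(profiles[have], function(p)
      p$per_marker_gc[[sym]] < p$total_gc, TRUE)
    data.frame(symbol = sym, n_below = sum(below),
               n_above_or_equal = sum(!below),
               fraction_below = if (length(below)) mean(below) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Notched-boxplot median interval
#'
#' The standard McGill rule `median +/- 1.57 * IQR / sqrt(n)` with
#' linear-interpolation quantiles; disjoint notches of two samples are
#' strong evidence of differing medians.
#'
#' @param sample Numeric vector, `n >= 2` (a warning below `n = 5`).
#' @return Numeric `c(lo, hi)`.
#' @export
notch_interval <- function(sample) {
  n <- length(sample)
  if (n < 2L) stop("notch interval needs at least two observations")
  if (n < 5L) warning("notch interval is unreliable below n = 5")
  med <- stats::median(sample)
  iqr <- stats::IQR(sample, type = 7)
  half <- 1.57 * iqr / sqrt(n)
  c(lo = med - half, hi = med + half)
}

#' Do two samples' medians differ by the notch rule?
#'
#' @param s1,s2 Numeric vectors.
#' @return `TRUE` iff the two notch intervals are disjoint.
#' @export
medians_differ <- function(s1, s2) {
  a <- notch_interval(s1)
  b <- notch_interval(s2)
  a["hi"] < b["lo"] || b["hi"] < a["lo"]
}

#' Cohort genome summary
#'
#' Per-genome assembly length and genome-wide GC, with cohort
#' min/max/mean/median of both. Lengths are reported in Mb to two decimals
#' (raw base-pair lengths are retained).
#'
#' @param genomes List of [genome_record()] objects.
#' @return List of class `genome_summary`: `per_genome` (data frame) and
#'   `cohort` (data frame of statistics for length_mb and gc).
#' @export
summarize_cohort <- function(genomes) {
  if (!length(genomes)) stop("no genomes supplied")
  per <- do.call(rbind, lapply(genomes, function(g) {
    len <- sum(nchar(g$contigs))
    data.frame(genome_id = g$genome_id, label = g$label, length_bp = len,
               length_mb = round(len / 1e6, 2),
               gc = gc_fraction(paste(g$contigs, collapse = "")))
  }))
  stat <- function(x) c(min = min(x), max = max(x), mean = mean(x),
                        median = stats::median(x))
  cohort <- rbind(length_mb = stat(per$length_bp / 1e6),
                  gc = stat(per$gc))
  structure(list(per_genome = per, cohort = as.data.frame(cohort)),
            class = "genome_summary")
}

#' @export
print.genome_summary <- function(x, ...) {
  cat("<genome_summary> ", nrow(x$per_genome), " genomes\n", sep = "")
  print(round(x$cohort, 4))
  invisible(x)
}
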