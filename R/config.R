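# Pipeline configuration: one flat set of knobs shared by every stage.

#' Pipeline configuration
#'
#' Defaults mirror the published protocol: a 40% nucleotide-identity mining
#' cut-off, 100 bootstrap replicates from random seed 1, a strict 50%
#' majority-rule consensus, and support audits at the 70% level.
#'
#' @param min_similarity Minimum global nucleotide alignment identity for a
#'   CDS to count as a marker ortholog (fraction, default 0.40).
#' @param n_bootstrap Bootstrap replicates (default 100).
#' @param rng_seed Seed for all stochastic steps (default 1).
#' @param consensus_threshold Majority-rule threshold; bipartitions must
#'   occur in strictly more than this fraction of replicates (default 0.5).
#' @param support_audit_threshold Integer percent used when counting
#'   well-supported nodes (default 70).
#' @param genetic_code NCBI translation table; only the bacterial table 11
#'   is supported.
#' @param gap_threshold,score_threshold Column-trimming rules: a column is
#'   dropped when its gap fraction exceeds `gap_threshold` or its
#'   cross-aligner consistency score falls below `score_threshold`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(min_similarity = 0.40, n_bootstrap = 100L,
                            rng_seed = 1L, consensus_threshold = 0.50,
                            support_audit_threshold = 70L,
                            genetic_code = 11L, gap_threshold = 0.9,
                            score_threshold = 0.5) {
  stopifnot(min_similarity > 0, min_similarity <= 1,
            n_bootstrap >= 1,
            consensus_threshold >= 0.5, consensus_threshold < 1,
            gap_threshold > 0, gap_threshold <= 1,
            score_threshold >= 0, score_threshold <= 1)
  if (as.integer(genetic_code) != 11L)
    stop("only the bacterial genetic code (table 11) is supported")
  structure(list(min_similarity = min_similarity,
                 n_bootstrap = as.integer(n_bootstrap),
                 rng_seed = as.integer(rng_seed),
                 consensus_threshold = consensus_threshold,
                 support_audit_threshold = as.integer(support_audit_threshold),
                 genetic_code = 11L,
                 gap_threshold = gap_threshold,
                 score_threshold = score_threshold),
            class = "pipeline_config")
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value` (comments with `#`) override the defaults
#' of [pipeline_config()].
#'
#' @param path Config file.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[1]), "")
  vals <- vapply(kv, function(x) trimws(paste(x[-1], collapse = "=")), "")
  allowed <- names(formals(pipeline_config))
  bad <- setdiff(keys, allowed)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  args <- lapply(vals, function(v) as.numeric(v))
  names(args) <- keys
  do.call(pipeline_config, args)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (k in names(x)) cat(sprintf("  %-24s %s\n", k, format(x[[k]])))
  invisible(x)
}
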