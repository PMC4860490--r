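# End-to-end drivers: from annotated genomes to consensus trees, congruence
# statistics and GC reports.

#' Alignment-to-consensus tree stage
#'
#' Builds the parameter ensemble, selects the most consistent member, trims
#' it, infers the corrected-distance NJ tree, runs the bootstrap, and takes
#' the strict majority-rule consensus.
#'
#' @param seqs Named character vector of unaligned sequences (concatenated
#'   marker proteins, or 16S nucleotide sequences).
#' @param config A [pipeline_config()].
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @param n_members Ensemble size (default 5).
#' @return List: `ensemble`, `selection` (from [consistency_select()]),
#'   `alignment` (trimmed [msa()]), `tree` (point-estimate NJ tree),
#'   `bootstrap` (replicate trees), `consensus` (supported consensus tree).
#' @export
build_marker_tree <- function(seqs, config = pipeline_config(),
                              alphabet = c("protein", "nucleotide"),
                              n_members = 5L) {
  alphabet <- match.arg(alphabet)
  ens <- build_ensemble(seqs, n_members, alphabet)
  sel <- consistency_select(ens)
  trimmed <- trim_alignment(sel$msa, sel$profile, config$gap_threshold,
                            config$score_threshold)
  type <- if (alphabet == "protein") "protein" else "nucleotide"
  boots <- bootstrap_trees(trimmed, config$n_bootstrap, config$rng_seed,
                           type)
  list(ensemble = ens, selection = sel, alignment = trimmed,
       tree = tree_from_msa(trimmed, type), bootstrap = boots,
       consensus = majority_consensus(boots, config$consensus_threshold))
}

#' Run the full glycolysis-marker pipeline over a cohort
#'
#' Mines every genome for the nine glycolysis markers and the 16S rRNA
#' gene, builds the concatenated-protein and 16S consensus trees, audits
#' bootstrap supports, compares the two trees, and computes GC profiles
#' and cohort summaries.
#'
#' @param genomes List of [genome_record()] objects.
#' @param db Marker reference database ([read_marker_db()] layout).
#' @param config A [pipeline_config()].
#' @param groups Optional group map (data frame `label`, `group`) to assess
#'   monophyly on both consensus trees.
#' @return List of class `glyco_pipeline` with components `mining`,
#'   `concat_tree`, `tree_16s`, `support_audit`, `branch_length_sums`,
#'   `comparison` (RF between the consensus trees), `monophyly`,
#'   `gc_profiles`, `gc_trend`, `cohort_summary`.
#' @export
run_pipeline <- function(genomes, db, config = pipeline_config(),
                         groups = NULL) {
  mining <- mine_cohort(genomes, db, config)
  concat_tree <- build_marker_tree(mining$concat, config, "protein")
  tree_16s <- NULL
  if (length(mining$seqs_16s) >= 3L)
    tree_16s <- build_marker_tree(mining$seqs_16s, config, "nucleotide")

  audit <- list(concat = count_supports_ge(concat_tree$consensus,
                                           config$support_audit_threshold))
  sums <- list(concat = sum_branch_lengths(concat_tree$consensus))
  comparison <- NULL
  if (!is.null(tree_16s)) {
    audit$s16 <- count_supports_ge(tree_16s$consensus,
                                   config$support_audit_threshold)
    sums$s16 <- sum_branch_lengths(tree_16s$consensus)
    if (setequal(concat_tree$consensus$tip.label,
                 tree_16s$consensus$tip.label))
      comparison <- robinson_foulds(concat_tree$consensus,
                                    tree_16s$consensus)
  }

  monophyly <- NULL
  if (!is.null(groups)) {
    monophyly <- list(concat = assess_group_monophyly(concat_tree$consensus,
                                                      groups))
    if (!is.null(tree_16s))
      monophyly$s16 <- assess_group_monophyly(tree_16s$consensus, groups)
  }

  labels <- vapply(genomes, `[[`, "", "label")
  profiles <- lapply(seq_along(genomes), function(i) {
    h <- mining$hits[[labels[i]]]
    h16 <- mining$hits_16s[[labels[i]]]
    if (!is.null(h16)) h <- c(h, list(rrs16S = h16))
    gc_profile(genomes[[i]], h)
  })
  names(profiles) <- labels

  structure(list(mining = mining, concat_tree = concat_tree,
                 tree_16s = tree_16s, support_audit = audit,
                 branch_length_sums = sums, comparison = comparison,
                 monophyly = monophyly, gc_profiles = profiles,
                 gc_trend = gene_vs_genome_trend(profiles),
                 cohort_summary = summarize_cohort(genomes)),
            class = "glyco_pipeline")
}

#' @export
print.glyco_pipeline <- function(x, ...) {
  cat("<glyco_pipeline>\n")
  cat("  genomes:", nrow(x$cohort_summary$per_genome), "\n")
  cat("  concatenated consensus: ",
      length(x$concat_tree$consensus$tip.label), " leaves, ",
      x$support_audit$concat$count, " nodes with support >= threshold\n",
      sep = "")
  if (!is.null(x$tree_16s))
    cat("  16S consensus: ", x$support_audit$s16$count,
        " nodes with support >= threshold\n", sep = "")
  if (!is.null(x$comparison))
    cat("  concat vs 16S RF: ", x$comparison$rf, " (normalized ",
        round(x$comparison$normalized, 3), ")\n", sep = "")
  invisible(x)
}
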