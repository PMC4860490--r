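# Cross-aligner consistency: score each column of a focal alignment by how
# often the other ensemble members reproduce its aligned residue pairs, pick
# the most consistent member, and trim poorly supported or gap-heavy
# columns (the role trimAl's compareset/automated1 played in the original
# protocol, re-specified as an explicit rule).

# per-row residue position indices per column (0 = gap)
residue_positions <- function(m) {
  t(apply(m != "-", 1, cumsum)) * (m != "-")
}

#' Consistency profile of one alignment against the rest of an ensemble
#'
#' For each column of `focal`, every aligned residue pair (two rows, both
#' ungapped) is checked against each other member: the pair counts as
#' reproduced when that member aligns the same two residues (identified by
#' their ungapped positions) into one column. The column score is the mean
#' reproduced fraction over its residue pairs; columns with fewer than two
#' residues are vacuously consistent (score 1).
#'
#' @param focal A [msa()].
#' @param others List of [msa()] objects over the same label set.
#' @return List of class `consistency_profile`: `column_scores`,
#'   `gap_fraction`, `overall` (mean column score), `source`.
#' @export
consistency_profile <- function(focal, others) {
  if (length(others) < 1L) stop("need at least one other ensemble member")
  mf <- msa_matrix(focal)
  for (o in others) if (!setequal(o$labels, focal$labels))
    stop("ensemble members disagree on the taxon label set")
  rows <- rownames(mf)
  pf <- residue_positions(mf)
  L <- ncol(mf)
  # For each other member and ordered row pair (a,b): partner[pos_a] = pos_b
  # when that member aligns residue pos_a of row a with a residue of row b.
  partner_maps <- lapply(others, function(o) {
    mo <- msa_matrix(o)[rows, , drop = FALSE]
    po <- residue_positions(mo)
    po
  })
  score_sum <- numeric(L)
  pair_count <- numeric(L)
  nr <- length(rows)
  for (a in seq_len(nr - 1L)) for (b in (a + 1L):nr) {
    both <- pf[a, ] > 0L & pf[b, ] > 0L
    if (!any(both)) next
    pa <- pf[a, both]
    pb <- pf[b, both]
    agree <- numeric(sum(both))
    for (k in seq_along(partner_maps)) {
      po <- partner_maps[[k]]
      # map: position of row a -> column index in member k
      cols_a <- integer(max(pa))
      nz <- po[a, ] > 0L
      cols_a[po[a, nz]] <- which(nz)
      colk <- cols_a[pa]
      agree <- agree + as.numeric(po[b, colk] == pb)
    }
    frac <- agree / length(partner_maps)
    score_sum[both] <- score_sum[both] + frac
    pair_count[both] <- pair_count[both] + 1
  }
  scores <- ifelse(pair_count > 0, score_sum / pmax(pair_count, 1), 1)
  structure(list(column_scores = scores,
                 gap_fraction = msa_gap_fraction(focal),
                 overall = mean(scores), source = focal$source),
            class = "consistency_profile")
}

#' Select the most consistent ensemble member
#'
#' Scores every member against the others and returns the one with the
#' highest overall consistency; ties resolve to the earliest member.
#'
#' @param ensemble List of >= 2 [msa()] objects over one label set.
#' @return List with `msa` (the chosen member), `profile` (its
#'   [consistency_profile()]), and `overall` (numeric vector of every
#'   member's overall score).
#' @export
consistency_select <- function(ensemble) {
  if (length(ensemble) < 2L)
    stop("consistency selection needs at least two ensemble members")
  profiles <- lapply(seq_along(ensemble), function(i)
    consistency_profile(ensemble[[i]], ensemble[-i]))
  overall <- vapply(profiles, `[[`, 0, "overall")
  best <- which.max(overall)  # ties -> first
  list(msa = ensemble[[best]], profile = profiles[[best]],
       overall = overall, chosen = best)
}

#' Trim an alignment by gap fraction and consistency score
#'
#' Drops every column whose gap fraction exceeds `gap_threshold` or whose
#' consistency score falls below `score_threshold`; surviving columns keep
#' their relative order. A per-column partition map (marker symbol per
#' column), when supplied, is subset alongside so concatenation boundaries
#' survive trimming.
#'
#' @param x A [msa()].
#' @param profile Its [consistency_profile()].
#' @param gap_threshold,score_threshold Trimming rules (defaults 0.9, 0.5).
#' @param column_partition Optional character vector, length
#'   `x$n_columns`.
#' @return The trimmed [msa()]; when `column_partition` is given, the
#'   trimmed map is attached as attribute `"column_partition"`.
#' @export
trim_alignment <- function(x, profile, gap_threshold = 0.9,
                           score_threshold = 0.5, column_partition = NULL) {
  if (length(profile$column_scores) != x$n_columns)
    stop("profile was not computed for this alignment")
  keep <- profile$gap_fraction <= gap_threshold &
    profile$column_scores >= score_threshold
  if (!any(keep))
    stop("trimming removed every column; relax gap_threshold or ",
         "score_threshold")
  m <- msa_matrix(x)[, keep, drop = FALSE]
  out <- msa(stats::setNames(apply(m, 1, paste, collapse = ""),
                             rownames(m)),
             source = paste0(x$source, "+trimmed"))
  if (!is.null(column_partition)) {
    stopifnot(length(column_partition) == length(keep))
    attr(out, "column_partition") <- column_partition[keep]
  }
  attr(out, "kept_columns") <- which(keep)
  # profile restricted to surviving columns, so trimming can be re-applied
  attr(out, "profile") <- structure(
    list(column_scores = profile$column_scores[keep],
         gap_fraction = profile$gap_fraction[keep],
         overall = mean(profile$column_scores[keep]),
         source = out$source),
    class = "consistency_profile")
  out
}
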