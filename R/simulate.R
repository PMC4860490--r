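# Synthetic annotated genomes: the nine marker CDSs plus a 16S-like gene
# evolved along a known Yule phylogeny, embedded in random intergenic
# sequence hitting a genome-wide GC target. Gives every pipeline stage a
# download-free fixture with full ground truth.

#' Simulation configuration
#'
#' Defaults mirror the study system at desk scale: nine marker proteins
#' totalling ~3,350 aa (the real concatenations span roughly 3,200-3,500
#' aa), a ~1.55 kb 16S gene evolving at a fifth of the protein-gene rate,
#' genomes of 230 kb (a tenth of the ~2.3 Mb genus average) at 60% GC, and
#' per-gene GC targets slightly above the genome-wide value except for
#' `tpi` and the 16S gene, which sit below it (the compositional trend the
#' analysis is designed to detect).
#'
#' @param n_taxa Number of leaf genomes (>= 3).
#' @param birth_rate Yule branching rate per lineage.
#' @param marker_lengths_aa Named amino-acid lengths of the nine ancestral
#'   marker proteins (including the initial Met, excluding the stop).
#' @param len_16s Length of the ancestral 16S-like gene (nt).
#' @param subst_rate Nucleotide substitutions per site per unit branch
#'   length for the protein genes.
#' @param rate_16s_factor Rate multiplier for the 16S gene.
#' @param marker_gc Named per-marker GC targets (stationary composition of
#'   the substitution process), `rrs16S` included.
#' @param genome_length Total genome length (bp).
#' @param genome_gc Genome-wide GC target; realized GC lands within 0.005.
#' @param rng_seed Seed driving the whole simulation.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_taxa = 10L, birth_rate = 1,
                       marker_lengths_aa = c(pgm = 505L, pgi = 430L,
                                             fba = 325L, tpi = 245L,
                                             gap = 330L, pgk = 390L,
                                             gpm = 230L, eno = 425L,
                                             pyk = 470L),
                       len_16s = 1550L, subst_rate = 0.05,
                       rate_16s_factor = 0.2,
                       marker_gc = c(pgm = 0.62, pgi = 0.62, fba = 0.62,
                                     gap = 0.62, pgk = 0.62, gpm = 0.62,
                                     eno = 0.62, pyk = 0.62, tpi = 0.57,
                                     rrs16S = 0.58),
                       genome_length = 230000L, genome_gc = 0.60,
                       rng_seed = 1L) {
  stopifnot(n_taxa >= 3L, birth_rate > 0, all(marker_lengths_aa > 0),
            len_16s > 0, subst_rate >= 0, rate_16s_factor >= 0,
            all(marker_gc > 0 & marker_gc < 1),
            genome_gc > 0, genome_gc < 1)
  defs <- glycolysis_markers()
  if (!setequal(names(marker_lengths_aa), defs$symbol))
    stop("marker_lengths_aa must name exactly the nine protein markers")
  if (!setequal(names(marker_gc), c(defs$symbol, "rrs16S")))
    stop("marker_gc must name the nine protein markers and rrs16S")
  structure(list(n_taxa = as.integer(n_taxa), birth_rate = birth_rate,
                 marker_lengths_aa = marker_lengths_aa,
                 len_16s = as.integer(len_16s), subst_rate = subst_rate,
                 rate_16s_factor = rate_16s_factor, marker_gc = marker_gc,
                 genome_length = as.integer(genome_length),
                 genome_gc = genome_gc, rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' Simulate a Yule (pure-birth) tree
#'
#' Exponential waiting times with total rate `k * rate` while `k` lineages
#' are extant; leaves are labelled `T001`, `T002`, ... in order of origin
#' and the tree is extended by one further exponential interval after the
#' last speciation so pendant edges are positive.
#'
#' @param n_taxa Number of leaves (>= 3).
#' @param rate Branching rate per lineage.
#' @param seed RNG seed.
#' @return A rooted binary `ape::phylo` tree.
#' @export
simulate_tree <- function(n_taxa, rate = 1, seed = 1L) {
  if (n_taxa < 3L) stop("need at least three taxa")
  with_seed(seed, {
    birth <- c(0, 0)           # birth time of each lineage (node)
    split_time <- c(NA, NA)    # time it split, NA while extant
    kids <- list(NULL, NULL)
    active <- c(1L, 2L)        # the root's two children start at t = 0
    t <- 0
    while (length(active) < n_taxa) {
      k <- length(active)
      t <- t + stats::rexp(1, k * rate)
      parent <- active[sample.int(k, 1)]
      id1 <- length(birth) + 1L
      id2 <- id1 + 1L
      birth <- c(birth, t, t)
      split_time <- c(split_time, NA, NA)
      split_time[parent] <- t
      kids <- c(kids, list(NULL), list(NULL))  # extend for id1, id2
      kids[[parent]] <- c(id1, id2)
      active <- c(setdiff(active, parent), id1, id2)
    }
    t_end <- t + stats::rexp(1, n_taxa * rate)
    active <- sort(active)
    leaf_label <- stats::setNames(sprintf("T%03d", seq_along(active)),
                                  active)
    nwk <- function(id) {
      if (is.null(kids[[id]])) {
        sprintf("%s:%.15g", leaf_label[[as.character(id)]],
                t_end - birth[id])
      } else {
        sprintf("(%s,%s):%.15g", nwk(kids[[id]][1]), nwk(kids[[id]][2]),
                split_time[id] - birth[id])
      }
    }
    ape::read.tree(text = sprintf("(%s,%s);", nwk(1L), nwk(2L)))
  })
}

#' Partition a tree's leaves into k clades
#'
#' Deterministically cuts a rooted tree into `k` groups by repeatedly
#' splitting the largest current clade at its root node (ties to the
#' smaller node id). Every group is a clade of the input tree, so the
#' partition serves as a ground-truth group map for monophyly checks.
#'
#' @param tree A rooted `ape::phylo` tree.
#' @param k Number of groups (1 to the number of leaves).
#' @return Named character vector `label -> group` (groups `G1` ... `Gk`).
#' @export
groups_from_tree <- function(tree, k) {
  nt <- length(tree$tip.label)
  stopifnot(k >= 1, k <= nt)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  clade_tips <- function(node) {
    if (node <= nt) return(tree$tip.label[node])
    unlist(lapply(children[[as.character(node)]], clade_tips))
  }
  roots <- nt + 1L
  while (length(roots) < k) {
    sizes <- vapply(roots, function(r) length(clade_tips(r)), 0L)
    splittable <- roots[sizes > 1L]
    if (!length(splittable)) break
    pick <- splittable[order(-sizes[match(splittable, roots)],
                             splittable)][1]
    roots <- c(setdiff(roots, pick), children[[as.character(pick)]])
    roots <- sort(roots)
  }
  out <- character(0)
  for (i in seq_along(roots)) {
    tips <- clade_tips(roots[i])
    out[tips] <- sprintf("G%d", i)
  }
  out
}

# ---- sequence evolution --------------------------------------------------

NT4 <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# sample n bases (integer codes 1..4) with GC target gc
sample_bases <- function(n, gc) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)  # A C G T
  sample.int(4L, n, replace = TRUE, prob = probs)
}

# Expected GC fraction of a codon drawn base-wise at per-base GC `g` with
# stop codons rejected. Rejecting the AT-rich stops (TAA/TAG/TGA) pushes
# realized GC above g, so coding sequences are sampled at a calibrated g
# solving expected_codon_gc(g) = target.
expected_codon_gc <- function(g) {
  base_p <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
  total_p <- 0
  total_gc <- 0
  for (b1 in NT4) for (b2 in NT4) for (b3 in NT4) {
    cod <- paste0(b1, b2, b3)
    if (cod %in% STOP_CODONS) next
    p <- base_p[b1] * base_p[b2] * base_p[b3]
    total_p <- total_p + p
    total_gc <- total_gc + p * sum(c(b1, b2, b3) %in% c("G", "C"))
  }
  unname(total_gc / (3 * total_p))
}

calibrated_coding_gc <- function(target) {
  stats::uniroot(function(g) expected_codon_gc(g) - target,
                 lower = 0.01, upper = 0.99, tol = 1e-10)$root
}

codon_str <- function(v) paste(NT4[v], collapse = "")

# ancestral CDS of aa length L (incl. start Met): ATG + (L-1) non-stop
# codons at the GC bias + TAA
ancestral_cds <- function(len_aa, gc) {
  out <- integer(3L * (len_aa + 1L))
  out[1:3] <- c(1L, 4L, 3L)  # ATG
  i <- 2L
  while (i <= len_aa) {
    cod <- sample_bases(3L, gc)
    if (codon_str(cod) %in% STOP_CODONS) next
    out[(3L * i - 2L):(3L * i)] <- cod
    i <- i + 1L
  }
  out[(3L * len_aa + 1L):(3L * len_aa + 3L)] <- c(4L, 1L, 1L)  # TAA
  out
}

# evolve an integer-coded sequence along one branch. Substitution
# probability per site is 1 - exp(-rate * len); the replacement base is
# drawn from the marker's stationary composition (renormalized without the
# current base). For coding sequences the start and stop codons are frozen
# and substitutions creating an internal stop are rejected.
evolve_branch <- function(seq, rate, len, gc, coding = TRUE) {
  p <- 1 - exp(-rate * len)
  if (p <= 0) return(seq)
  n <- length(seq)
  mutable <- if (coding) 4L:(n - 3L) else 1L:n
  hit <- mutable[stats::runif(length(mutable)) < p]
  if (!length(hit)) return(seq)
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  new <- seq
  for (s in hit) {
    cur <- new[s]
    pr <- probs
    pr[cur] <- 0
    new[s] <- sample.int(4L, 1L, prob = pr)
  }
  if (coding) {
    # revert any codon that became a stop
    codon_of <- ((hit - 1L) %/% 3L) + 1L
    for (cd in unique(codon_of)) {
      pos <- (3L * cd - 2L):(3L * cd)
      if (codon_str(new[pos]) %in% STOP_CODONS) new[pos] <- seq[pos]
    }
  }
  new
}

#' Evolve synthetic genomes along a tree
#'
#' Ancestral marker CDSs (and a 16S-like gene) are mutated along every
#' branch of `tree` under a codon-preserving substitution model; each leaf
#' genome embeds its ten markers, shuffled and on random strands, in random
#' intergenic sequence whose composition is solved so the genome-wide GC
#' hits the configured target.
#'
#' @param tree A rooted `ape::phylo` (e.g. from [simulate_tree()]); leaf
#'   labels become genome labels.
#' @param cfg A [sim_config()].
#' @return Object of class `glyco_sim`: `genomes` (list of
#'   [genome_record()]), `truth` (data frame of planted marker coordinates,
#'   0-based half-open, forward strand), `marker_seqs` (per-leaf true
#'   marker sequences, coding strand), `tree`, `cfg`.
#' @export
evolve_genomes <- function(tree, cfg = sim_config()) {
  defs <- glycolysis_markers()
  syms <- defs$symbol
  # per-base sampling GC calibrated so post-rejection coding GC hits the
  # marker's target; the 16S gene has no codon structure and needs none
  gc_bias <- vapply(syms, function(s)
    calibrated_coding_gc(cfg$marker_gc[[s]]), 0)
  gc_bias[["rrs16S"]] <- cfg$marker_gc[["rrs16S"]]
  with_seed(cfg$rng_seed, {
    anc <- lapply(syms, function(s)
      ancestral_cds(cfg$marker_lengths_aa[[s]], gc_bias[[s]]))
    names(anc) <- syms
    anc$rrs16S <- sample_bases(cfg$len_16s, gc_bias[["rrs16S"]])

    nt <- length(tree$tip.label)
    root <- nt + 1L
    seqs_at <- vector("list", nt + tree$Nnode)
    seqs_at[[root]] <- anc
    pre <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(pre$edge))) {
      par <- pre$edge[e, 1]; ch <- pre$edge[e, 2]
      len <- pre$edge.length[e]
      parent_seqs <- seqs_at[[par]]
      child <- lapply(names(parent_seqs), function(s) {
        coding <- s != "rrs16S"
        rate <- cfg$subst_rate * if (coding) 1 else cfg$rate_16s_factor
        evolve_branch(parent_seqs[[s]], rate, len, gc_bias[[s]], coding)
      })
      names(child) <- names(parent_seqs)
      seqs_at[[ch]] <- child
    }

    genomes <- list()
    truth <- list()
    marker_seqs <- list()
    for (leaf in seq_len(nt)) {
      label <- tree$tip.label[leaf]
      seqs <- seqs_at[[leaf]]
      marker_seqs[[label]] <- lapply(seqs, function(v)
        paste(NT4[v], collapse = ""))
      g <- assemble_genome(label, seqs, cfg)
      genomes[[label]] <- g$genome
      truth[[label]] <- g$truth
    }
    structure(list(genomes = genomes,
                   truth = do.call(rbind, truth),
                   marker_seqs = marker_seqs,
                   tree = tree, cfg = cfg),
              class = "glyco_sim")
  })
}

# place the ten markers (shuffled, random strands) into intergenic filler
# solved to hit the genome GC target
assemble_genome <- function(label, seqs, cfg) {
  ord <- sample(names(seqs))
  strands <- sample(c("+", "-"), length(ord), replace = TRUE)
  el_lens <- vapply(seqs[ord], length, 0L)
  total_el <- sum(el_lens)
  n_gaps <- length(ord) + 1L
  total_int <- cfg$genome_length - total_el
  if (total_int < n_gaps * 20L)
    stop("genome_length too small for the marker complement")
  gc_el <- sum(vapply(seqs, function(v) sum(v == 2L | v == 3L), 0L))
  need_gc <- cfg$genome_gc * cfg$genome_length - gc_el
  g_int <- need_gc / total_int
  if (g_int < 0.02 || g_int > 0.98)
    stop("infeasible genome GC target ", cfg$genome_gc,
         " given the marker composition")
  # exact intergenic GC count, split into n_gaps segments
  n_gc <- round(g_int * total_int)
  pool <- integer(total_int)
  gc_pos <- sample.int(total_int, n_gc)
  pool[gc_pos] <- sample(c(2L, 3L), n_gc, replace = TRUE)
  pool[pool == 0L] <- sample(c(1L, 4L), total_int - n_gc, replace = TRUE)
  w <- stats::runif(n_gaps) + 0.2
  cuts <- floor(cumsum(w) / sum(w) * total_int)
  seg_len <- diff(c(0L, cuts))
  seg_end <- cumsum(seg_len)
  seg_start <- c(0L, head(seg_end, -1L))

  contig <- integer(cfg$genome_length)
  pos <- 0L
  truth <- list()
  cds_rows <- list()
  for (i in seq_along(ord)) {
    ig <- pool[(seg_start[i] + 1L):seg_end[i]]
    contig[(pos + 1L):(pos + length(ig))] <- ig
    pos <- pos + length(ig)
    v <- seqs[[ord[i]]]
    if (strands[i] == "-") v <- rev(5L - v)  # reverse complement in codes
    contig[(pos + 1L):(pos + length(v))] <- v
    start0 <- pos
    end0 <- pos + length(v)
    pos <- end0
    truth[[i]] <- data.frame(label = label, symbol = ord[i],
                             contig_id = paste0(label, "_c1"),
                             start = start0, end = end0,
                             strand = strands[i])
    if (ord[i] != "rrs16S") {
      enzyme <- glycolysis_markers(TRUE)
      cds_rows[[length(cds_rows) + 1L]] <- data.frame(
        contig_id = paste0(label, "_c1"), start = start0, end = end0,
        strand = strands[i],
        locus_tag = sprintf("%s_%04d", label, i),
        product = enzyme$enzyme[enzyme$symbol == ord[i]])
    }
  }
  ig <- pool[(seg_start[n_gaps] + 1L):seg_end[n_gaps]]
  contig[(pos + 1L):(pos + length(ig))] <- ig
  pos <- pos + length(ig)
  contig <- contig[seq_len(pos)]
  seq <- paste(NT4[contig], collapse = "")
  genome <- genome_record(genome_id = label, label = label,
                          contigs = stats::setNames(seq,
                                                    paste0(label, "_c1")),
                          cds_features = do.call(rbind, cds_rows))
  list(genome = genome, truth = do.call(rbind, truth))
}

#' Build a marker reference database from a simulation
#'
#' Uses the true marker sequences of the first `n_ref` leaves as the
#' reference set (the role the four reference species play on real data).
#'
#' @param sim A `glyco_sim`.
#' @param n_ref Number of reference genomes (default 4).
#' @return Marker database data frame ([read_marker_db()] layout).
#' @export
reference_db_from_sim <- function(sim, n_ref = 4L) {
  labels <- head(sim$tree$tip.label, n_ref)
  rows <- list()
  for (l in labels) {
    for (s in names(sim$marker_seqs[[l]])) {
      rows[[length(rows) + 1L]] <- data.frame(
        symbol = s, species = l, type = "nt",
        seq = sim$marker_seqs[[l]][[s]], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write simulated genomes and truth tables to a directory
#'
#' Emits one GenBank file per genome, the true tree (`true_tree.nwk`), the
#' planted-coordinate truth table (`truth.tsv`) and the reference database
#' (`marker_db.fasta`).
#'
#' @param sim A `glyco_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in sim$genomes)
    write_genbank(g, file.path(dir, paste0(g$label, ".gbk")))
  write_newick(sim$tree, file.path(dir, "true_tree.nwk"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_marker_db(reference_db_from_sim(sim),
                  file.path(dir, "marker_db.fasta"))
  invisible(dir)
}
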