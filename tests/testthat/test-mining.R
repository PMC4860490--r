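# Marker mining, translation, concatenation, 16S extraction.

# helper: genome with given CDS sequences planted on a filler contig
plant_genome <- function(cds_seqs, filler = 400, seed = 3) {
  set.seed(seed)
  pieces <- character(0)
  rows <- list()
  pos <- 0L
  for (i in seq_along(cds_seqs)) {
    ig <- rand_nt(filler)
    pieces <- c(pieces, ig, cds_seqs[i])
    start <- pos + filler
    end <- start + nchar(cds_seqs[i])
    pos <- end
    rows[[i]] <- data.frame(contig_id = "c1", start = start, end = end,
                            strand = "+",
                            locus_tag = sprintf("L%02d", i), product = "")
  }
  pieces <- c(pieces, rand_nt(filler))
  genome_record("g1", "B_test", c(c1 = paste(pieces, collapse = "")),
                do.call(rbind, rows))
}

ref_db <- function(...) {
  args <- list(...)
  do.call(rbind, lapply(names(args), function(sym)
    data.frame(symbol = sym, species = "ref", type = "nt",
               seq = args[[sym]], stringsAsFactors = FALSE)))
}

test_that("an identical CDS is found with similarity 1", {
  gene <- "ATGAAACCCGGGTTTACACCAGCAGGAGCAGCATAA"
  g <- plant_genome(c(gene))
  db <- ref_db(pgm = gene)
  h <- find_marker(g, "pgm", db)
  expect_equal(h$similarity, 1)
  expect_equal(h$nt_seq, gene)
  expect_equal(h$aa_seq, translate_cds(gene))
})

test_that("a CDS at ~30% identity is absent at the 40% cut-off", {
  set.seed(21)
  ref <- paste0("ATG", rand_nt(120), "TAA")
  # mutate ~70% of positions of the interior
  v <- strsplit(ref, "")[[1]]
  idx <- 3 + sample(120, 90)
  for (i in idx) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  # keep the frame stop-free so the fixture is a valid CDS
  mut <- paste(v, collapse = "")
  g <- plant_genome(c(mut))
  db <- ref_db(tpi = ref)
  # oracle: identity of the pair under an independent aligner
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(mut, ref, type = "overlap",
                                       substitutionMatrix = sub,
                                       gapOpening = 15, gapExtension = 6.66)
  # identity over the full alignment span, unaligned overhangs included
  pr <- Biostrings::pattern(aln)
  sr <- Biostrings::subject(aln)
  overhang <- (Biostrings::start(pr) - 1) + (Biostrings::start(sr) - 1) +
    (nchar(mut) - Biostrings::end(pr)) + (nchar(ref) - Biostrings::end(sr))
  oracle_id <- Biostrings::nmatch(aln) /
    (Biostrings::nchar(aln) + overhang)
  expect_lt(oracle_id, 0.40)
  expect_null(find_marker(g, "tpi", db))
})

test_that("the full-length homolog beats a half-length fragment", {
  gene <- paste0("ATG", paste(rep("GCAGGTGCATCA", 20), collapse = ""), "TAA")
  frag <- substr(gene, 1, nchar(gene) / 2)
  frag <- paste0(substr(frag, 1, nchar(frag) - nchar(frag) %% 3))
  g <- plant_genome(c(frag, gene))
  db <- ref_db(pgi = gene)
  # oracle: compare the two alignment scores independently
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = 5, mismatch = -4,
                                                  baseOnly = TRUE)
  sc <- function(q) Biostrings::pairwiseAlignment(
    q, gene, type = "overlap", substitutionMatrix = sub,
    gapOpening = 15, gapExtension = 6.66, scoreOnly = TRUE)
  expect_gt(sc(gene), sc(frag))
  h <- find_marker(g, "pgi", db)
  expect_equal(h$nt_seq, gene)
})

test_that("an unannotated genome is an explicit error, not absent", {
  g <- genome_record("g", "B_test", c(c1 = "ACGTACGTACGT"))
  db <- ref_db(pgm = "ATGAAATAA")
  expect_error(find_marker(g, "pgm", db), "unannotated")
})

test_that("translation handles starts, stops and frame errors", {
  expect_equal(translate_cds("ATGAAATAA"), "MK")
  expect_equal(translate_cds("GTGAAATAA"), "MK")
  expect_equal(translate_cds("TTGAAA"), "MK")
  expect_error(translate_cds("ATGTAAAAA"), "internal stop")
  expect_error(translate_cds("ATGAA"), "frame")
  expect_error(translate_cds("ATGANA"), "outside")
})

test_that("concatenation follows pathway order regardless of input order", {
  aa <- c(pgm = "AAAA", pgi = "CCCC", fba = "DDDD", tpi = "EEEE",
          gap = "FFFF", pgk = "GGGG", gpm = "HHHH", eno = "IIII",
          pyk = "KKKK")
  hits <- lapply(sort(names(aa)), function(s)
    structure(list(genome_id = "g", symbol = s, nt_seq = "",
                   aa_seq = aa[[s]]), class = "marker_hit"))
  cc <- concatenate_markers(hits)
  expect_equal(cc$partitions$symbol,
               c("pgm", "pgi", "fba", "tpi", "gap", "pgk", "gpm", "eno",
                 "pyk"))
  expect_equal(cc$seq, paste(aa[cc$partitions$symbol], collapse = ""))
  expect_equal(nchar(cc$seq), 36L)
  expect_equal(cc$partitions$end - cc$partitions$start + 1L, rep(4L, 9))

  drop_eno <- hits[vapply(hits, `[[`, "", "symbol") != "eno"]
  expect_error(concatenate_markers(drop_eno), "eno")
  expect_error(concatenate_markers(c(hits, hits[1])), "duplicate")
})

test_that("16S extraction finds the exact copy among mutated paralogs", {
  set.seed(31)
  ref <- rand_nt(300)
  mut <- strsplit(ref, "")[[1]]
  idx <- sample(300, 15)  # 5% mutated copy
  for (i in idx) mut[i] <- sample(setdiff(c("A", "C", "G", "T"), mut[i]), 1)
  mut <- paste(mut, collapse = "")
  contig <- paste0(rand_nt(200), mut, rand_nt(200), ref, rand_nt(200))
  g <- genome_record("g", "B_test", c(c1 = contig))
  db <- ref_db(rrs16S = ref)
  h <- extract_16s(g, db)
  expect_equal(h$nt_seq, ref)
  expect_equal(h$similarity, 1)
  expect_equal(h$start, 700L)
  expect_equal(h$end, 1000L)

  g2 <- genome_record("g2", "B_test", c(c1 = rand_nt(600)))
  expect_null(extract_16s(g2, db))
})

test_that("16S on the minus strand is located and reverse-complemented", {
  set.seed(33)
  ref <- rand_nt(300)
  contig <- paste0(rand_nt(150), reverse_complement(ref), rand_nt(150))
  g <- genome_record("g", "B_test", c(c1 = contig))
  h <- extract_16s(g, ref_db(rrs16S = ref))
  expect_equal(h$nt_seq, ref)
  expect_equal(h$strand, "-")
  expect_equal(h$start, 150L)
  expect_equal(h$end, 450L)
})

test_that("mining recovers every planted CDS exactly and deterministically", {
  sim <- small_sim()
  db <- small_db()
  cfg <- pipeline_config()
  for (label in names(sim$genomes)[1:3]) {
    g <- sim$genomes[[label]]
    m <- mine_genome(g, db, cfg)
    tru <- sim$truth[sim$truth$label == label &
                       sim$truth$symbol != "rrs16S", ]
    got <- m$report[match(tru$symbol, m$report$symbol), ]
    expect_equal(got$start, tru$start)
    expect_equal(got$end, tru$end)
    expect_equal(got$strand, tru$strand)
    # recovered sequences equal the planted coding sequences
    for (s in tru$symbol)
      expect_equal(m$hits[[s]]$nt_seq, sim$marker_seqs[[label]][[s]])
    # determinism: byte-identical reports on a second run
    m2 <- mine_genome(g, db, cfg)
    expect_identical(m2$report, m$report)
  }
})

test_that("strict mode names missing markers", {
  sim <- small_sim()
  g <- sim$genomes[[1]]
  db <- small_db()
  db2 <- db[db$symbol != "eno", ]
  expect_error(mine_genome(g, db2, pipeline_config()), "eno")
})
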