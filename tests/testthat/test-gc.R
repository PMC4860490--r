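# GC content, classification, trends, notch comparisons, cohort summaries.

test_that("gc_fraction counts G+C over unambiguous bases", {
  expect_equal(gc_fraction("ATGC"), 0.5)
  expect_equal(gc_fraction("GGCC"), 1.0)
  expect_equal(gc_fraction("GCNN"), 1.0)
  expect_equal(gc_fraction("atgc"), 0.5)
  expect_error(gc_fraction("NNNN"), "no unambiguous")
  expect_error(gc_fraction("ACGU"), "outside")
})

test_that("gc_fraction is strand-invariant and concatenation-consistent", {
  set.seed(8)
  for (i in 1:5) {
    s <- rand_nt(200)
    expect_equal(gc_fraction(s), gc_fraction(reverse_complement(s)))
    t <- rand_nt(117)
    both <- paste0(s, t)
    w <- c(200, 117)
    expect_equal(gc_fraction(both),
                 sum(w * c(gc_fraction(s), gc_fraction(t))) / sum(w))
  }
})

test_that("GC classification follows the band boundaries", {
  expect_equal(classify_gc(0.528), "low")
  expect_equal(classify_gc(0.60), "medium")
  expect_equal(classify_gc(0.567), "medium")  # half-open boundary
  expect_equal(classify_gc(0.613), "high")
  expect_equal(classify_gc(0.66), "high")
  expect_warning(lo <- classify_gc(0.40), "clamped")
  expect_equal(lo, "low")
  expect_warning(hi <- classify_gc(0.70), "clamped")
  expect_equal(hi, "high")
})

test_that("classification partitions any cohort", {
  set.seed(5)
  vals <- runif(60, 0.52, 0.66)
  cls <- vapply(vals, classify_gc, "")
  expect_equal(sum(table(factor(cls, c("low", "medium", "high")))), 60L)
})

test_that("per-marker GC trend counts genomes below their total GC", {
  # profiles with all markers equal to total -> fraction_below 0
  syms <- c(glycolysis_markers()$symbol, "rrs16S")
  mk_prof <- function(total, per) {
    structure(list(genome_id = "g", label = "g", total_gc = total,
                   per_marker_gc = per, gc_class = "medium"),
              class = "gc_profile")
  }
  eq <- lapply(1:4, function(i)
    mk_prof(0.6, stats::setNames(rep(0.6, 10), syms)))
  tr <- gene_vs_genome_trend(eq)
  expect_true(all(tr$fraction_below == 0))
  expect_equal(tr$symbol[10], "rrs16S")

  # planted: tpi below total in 8 of 10 genomes
  set.seed(9)
  profs <- lapply(1:10, function(i) {
    per <- stats::setNames(rep(0.62, 10), syms)
    per["tpi"] <- if (i <= 8) 0.55 else 0.65
    mk_prof(0.6, per)
  })
  tr2 <- gene_vs_genome_trend(profs)
  expect_equal(tr2$fraction_below[tr2$symbol == "tpi"], 0.8)
  expect_equal(tr2$n_below[tr2$symbol == "pgm"], 0L)

  # single genome: counts in {0, 1}
  tr3 <- gene_vs_genome_trend(profs[1])
  expect_true(all(tr3$n_below + tr3$n_above_or_equal == 1))
})

test_that("notch intervals implement the McGill rule", {
  set.seed(10)
  x <- runif(48, 0.58, 0.62)
  got <- notch_interval(x)
  expect_equal(unname(got["hi"] - got["lo"]),
               2 * 1.57 * stats::IQR(x) / sqrt(48))
  expect_equal(unname(got["lo"] + got["hi"]) / 2, stats::median(x))

  # identical samples never differ
  expect_false(medians_differ(x, x))
  # degenerate zero-IQR samples at distinct medians differ
  suppressWarnings(expect_true(medians_differ(rep(0.55, 3), rep(0.65, 3))))
  # symmetry
  y <- runif(48, 0.59, 0.63)
  expect_equal(medians_differ(x, y), medians_differ(y, x))
  expect_error(notch_interval(0.5), "at least two")
})

test_that("notch separation tracks spread at fixed median gap", {
  set.seed(14)
  tight1 <- rnorm(48, 0.60, 0.002)
  tight2 <- rnorm(48, 0.61, 0.002)
  expect_true(medians_differ(tight1, tight2))
  wide1 <- rnorm(48, 0.60, 0.05)
  wide2 <- rnorm(48, 0.61, 0.05)
  expect_false(medians_differ(wide1, wide2))
})

test_that("cohort summaries reduce to direct arithmetic", {
  g1 <- genome_record("g1", "B_one",
                      c(c1 = paste(rep("ATGC", 500000), collapse = "")))
  s1 <- summarize_cohort(list(g1))
  expect_equal(s1$per_genome$length_mb, 2.00)
  expect_equal(s1$per_genome$gc, 0.5)
  expect_true(all(s1$cohort["gc", ] == 0.5))

  g2 <- genome_record("g2", "B_two",
                      c(c1 = paste(rep("AT", 500000), collapse = "")))
  g3 <- genome_record("g3", "B_three",
                      c(c1 = paste(rep("GCAT", 750000), collapse = "")))
  s2 <- summarize_cohort(list(g2, g3))
  expect_equal(s2$cohort["length_mb", "mean"], 2.00)
  expect_equal(s2$cohort["length_mb", "median"], 2.00)

  # planted 10-genome cohort vs direct recomputation
  set.seed(15)
  lens <- sample(1000:5000, 10)
  gs <- lapply(seq_along(lens), function(i)
    genome_record(paste0("g", i), paste0("B_sp", i),
                  stats::setNames(rand_nt(lens[i]), "c1")))
  s3 <- summarize_cohort(gs)
  expect_equal(s3$cohort["length_mb", "min"], min(lens) / 1e6)
  expect_equal(s3$cohort["length_mb", "max"], max(lens) / 1e6)
  expect_equal(s3$cohort["length_mb", "mean"], mean(lens) / 1e6)
  expect_equal(s3$cohort["length_mb", "median"], median(lens) / 1e6)
  gcs <- vapply(gs, function(g) gc_fraction(g$contigs[[1]]), 0)
  expect_equal(s3$cohort["gc", "mean"], mean(gcs))
  expect_true(s3$cohort["gc", "min"] <= s3$cohort["gc", "median"] &&
                s3$cohort["gc", "median"] <= s3$cohort["gc", "max"])
})

test_that("gc profiles tie class to total GC and carry marker values", {
  sim <- small_sim()
  mined <- small_mined()
  g <- sim$genomes[[1]]
  label <- g$label
  hits <- c(mined$hits[[label]], list(rrs16S = mined$hits_16s[[label]]))
  p <- gc_profile(g, hits)
  expect_equal(p$total_gc, gc_fraction(g$contigs[[1]]))
  expect_equal(p$gc_class, classify_gc(p$total_gc))
  expect_equal(sort(names(p$per_marker_gc)),
               sort(c(glycolysis_markers()$symbol, "rrs16S")))
  expect_true(all(p$per_marker_gc >= 0 & p$per_marker_gc <= 1))
})
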