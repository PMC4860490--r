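# Distances, neighbor joining, bootstrap, consensus, and tree statistics.

test_that("distance corrections match their closed forms", {
  # protein: Kimura correction at p = 0.1
  m <- msa(c(a = paste(rep("A", 10), collapse = ""),
             b = paste(c(rep("A", 9), "C"), collapse = ""),
             c = paste(rep("A", 10), collapse = "")))
  D <- seq_distance_matrix(m, "protein")
  expect_equal(D["a", "b"], -log(1 - 0.1 - 0.2 * 0.01), tolerance = 1e-12)
  expect_equal(D["a", "b"], 0.10758, tolerance = 1e-4)
  expect_equal(D["a", "c"], 0)

  # nucleotide: Jukes-Cantor at p = 0.25
  m2 <- msa(c(a = "AAAAAAAA", b = "AAAAAACG", c = "AAAAAAAA"))
  D2 <- seq_distance_matrix(m2, "nucleotide")
  expect_equal(D2["a", "b"], -0.75 * log(1 - (4 / 3) * 0.25),
               tolerance = 1e-12)
  expect_equal(D2["a", "b"], 0.30410, tolerance = 1e-4)
})

test_that("saturated and degenerate pairs are handled", {
  # p = 1 is past the Kimura domain -> saturation replacement
  m <- msa(c(a = "AAAA", b = "CCCC", c = "AACC"))
  expect_warning(D <- seq_distance_matrix(m, "protein"), "saturated")
  expect_true(all(is.finite(D)))
  expect_equal(D["a", "b"], 2 * max(D[is.finite(D) & D != D["a", "b"]]))

  m2 <- msa(c(a = "AA--", b = "--CC", c = "AACC"))
  expect_error(seq_distance_matrix(m2, "protein"), "no ungapped")
})

test_that("three-taxon NJ solves the closed form", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  sp <- glycophylo:::tree_splits(tr)
  len <- setNames(sp$length, sp$key)
  expect_equal(unname(len["B"]), (3 + 5 - 4) / 2)  # x_B = 2
  expect_equal(unname(len["C"]), (4 + 5 - 3) / 2)  # x_C = 3
  expect_equal(sum(tr$edge.length), 6)             # x_A = 1
})

test_that("NJ recovers additive trees exactly up to 12 taxa", {
  set.seed(99)
  for (n in c(5, 8, 12)) {
    for (rep in 1:3) {
      true <- ape::rtree(n)
      true$edge.length <- true$edge.length + 0.05
      D <- ape::cophenetic.phylo(true)
      est <- neighbor_joining(D)
      expect_equal(robinson_foulds(est, true)$rf, 0L)
      # unrooted comparison: the two root edges of the rooted true tree
      # fuse into one, so compare leaf-to-leaf path lengths and totals
      expect_equal(ape::cophenetic.phylo(est)[rownames(D), rownames(D)],
                   D, tolerance = 1e-9)
      expect_equal(sum(est$edge.length), sum(true$edge.length),
                   tolerance = 1e-9)
    }
  }
})

test_that("NJ agrees with ape on generic matrices", {
  set.seed(12)
  for (rep in 1:3) {
    n <- 9
    M <- matrix(runif(n * n, 0.1, 1), n, n)
    D <- (M + t(M)) / 2
    diag(D) <- 0
    dimnames(D) <- list(letters[1:n], letters[1:n])
    est <- neighbor_joining(D)
    ref <- ape::nj(D)
    expect_equal(robinson_foulds(est, ref)$rf, 0L)
  }
})

test_that("equidistant taxa collapse deterministically with known length", {
  D <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(D) <- 0
  tr <- neighbor_joining(D)
  # every terminal edge 0.5, internal edge 0
  expect_equal(sum(tr$edge.length), 2)
  tr2 <- neighbor_joining(D)
  expect_identical(write_newick(tr), write_newick(tr2))
})

test_that("bootstrap replication is seed-deterministic", {
  sim <- small_sim()
  seqs <- small_mined()$concat
  m <- progressive_msa(seqs, align_params("protein"))
  b1 <- bootstrap_trees(m, n = 5, seed = 42, type = "protein")
  b2 <- bootstrap_trees(m, n = 5, seed = 42, type = "protein")
  expect_identical(lapply(b1, write_newick), lapply(b2, write_newick))
  b3 <- bootstrap_trees(m, n = 5, seed = 43, type = "protein")
  expect_false(identical(lapply(b1, write_newick),
                         lapply(b3, write_newick)))
})

test_that("uniform-column alignments give identical replicates", {
  # every column identical: resampling cannot change the alignment
  rows <- c(a = "AAAA", b = "CCCC", c = "GGGG", d = "TTTT")
  m <- msa(rows)
  base <- suppressWarnings(tree_from_msa(m, "nucleotide"))
  reps <- suppressWarnings(bootstrap_trees(m, 10, seed = 1,
                                           type = "nucleotide"))
  for (t in reps) expect_equal(robinson_foulds(t, base)$rf, 0L)
})

test_that("majority consensus keeps majorities and collapses conflict", {
  t1 <- read_newick("((A:1,B:1):1,(C:1,D:1):1,E:1);")
  t2 <- read_newick("((A:2,B:2):2,(C:2,E:2):2,D:2);")
  t3 <- read_newick("((A:3,B:3):3,(C:3,D:3):3,E:3);")

  cons <- majority_consensus(list(t1, t2, t3))
  sp <- glycophylo:::tree_splits(cons)
  # {A,B}|rest canonicalizes to the side not containing A
  key_ab <- paste(sort(c("C", "D", "E")), collapse = "\t")
  ab <- sp[sp$key == key_ab, ]
  expect_equal(nrow(ab), 1L)
  expect_equal(ab$support, 100)
  key_cd <- paste(sort(c("C", "D")), collapse = "\t")
  cd <- sp[sp$key == key_cd, ]
  expect_equal(cd$support, 67)  # round(200/3)
  # mean branch length over the trees containing the bipartition
  expect_equal(ab$length, mean(c(1, 2, 3)))
  expect_equal(cd$length, mean(c(1, 3)))

  # identical trees: same topology, all supports 100
  cons2 <- majority_consensus(list(t1, t1, t1, t1))
  expect_equal(robinson_foulds(cons2, t1)$rf, 0L)
  expect_true(all(glycophylo:::tree_supports(cons2) == 100,
                  na.rm = TRUE))

  # fully conflicting pair -> star tree
  s1 <- read_newick("((A,B),(C,D));")
  s2 <- read_newick("((A,C),(B,D));")
  star <- majority_consensus(list(s1, s2))
  expect_equal(length(glycophylo:::nontrivial_keys(star)), 0L)
})

test_that("consensus supports exceed the threshold and cap at 100", {
  run <- recovery_run()
  sup <- glycophylo:::tree_supports(run$res$concat_tree$consensus)
  sup <- sup[!is.na(sup)]
  expect_true(all(sup > 50 & sup <= 100))
})

test_that("branch-length sums match an independent edge-list oracle", {
  expect_equal(sum_branch_lengths(read_newick("(A:1,B:2);")), 3)
  expect_equal(sum_branch_lengths(read_newick("((A:1,B:1):2,C:3);")), 7)
  set.seed(4)
  tr <- ape::rtree(30)
  # oracle: pull the numbers straight out of the newick text
  txt <- write_newick(tr)
  nums <- as.numeric(unlist(regmatches(
    txt, gregexpr(":([0-9.eE+-]+)", txt))) |> sub(pattern = ":",
                                                  replacement = ""))
  expect_equal(sum_branch_lengths(tr), sum(nums), tolerance = 1e-8)
  tr$edge.length <- NULL
  expect_error(sum_branch_lengths(tr), "absent")
})

test_that("support audits count and range correctly", {
  tr <- read_newick("(((A,B)52:1,(C,D)70:1)100:1,E:1);")
  a <- count_supports_ge(tr, 70)
  expect_equal(a$count, 2L)
  expect_equal(a$min, 52)
  expect_equal(a$max, 100)
  expect_equal(count_supports_ge(tr, 0)$count, a$n_supported)
  expect_equal(count_supports_ge(tr, 101)$count, 0L)
  plain <- read_newick("((A,B),C);")
  expect_warning(res <- count_supports_ge(plain, 70), "no numeric")
  expect_equal(res$count, 0L)
})

test_that("Robinson-Foulds distance counts bipartition disagreements", {
  t1 <- read_newick("((((A,B),C),D),E);")
  t2 <- read_newick("((((A,C),B),D),E);")
  # each caterpillar has 2 nontrivial bipartitions: {A,B}/{A,C} differ,
  # {A,B,C} shared -> rf = 2
  expect_equal(robinson_foulds(t1, t2)$rf, 2L)
  expect_equal(robinson_foulds(t1, t2)$normalized, 0.5)
  expect_equal(robinson_foulds(t1, t1)$rf, 0L)

  bin <- read_newick("((A,B),(C,D),E);")
  star <- read_newick("(A,B,C,D,E);")
  rf <- robinson_foulds(bin, star)
  expect_equal(rf$rf, length(glycophylo:::nontrivial_keys(bin)))
  expect_equal(rf$normalized, 1)

  expect_error(robinson_foulds(t1, read_newick("((A,B),(C,F));")),
               "leaf sets differ")
})

test_that("RF agrees with phangorn and satisfies the metric axioms", {
  set.seed(77)
  for (rep in 1:4) {
    trees <- lapply(1:3, function(i) ape::rtree(8))
    # relabel to a common leaf set
    for (i in 1:3) trees[[i]]$tip.label <-
        paste0("t", match(trees[[i]]$tip.label, trees[[1]]$tip.label))
    d12 <- robinson_foulds(trees[[1]], trees[[2]])$rf
    d21 <- robinson_foulds(trees[[2]], trees[[1]])$rf
    d13 <- robinson_foulds(trees[[1]], trees[[3]])$rf
    d23 <- robinson_foulds(trees[[2]], trees[[3]])$rf
    expect_equal(d12, d21)                      # symmetry
    expect_lte(d13, d12 + d23)                  # triangle
    expect_equal(robinson_foulds(trees[[1]], trees[[1]])$rf, 0L)
    expect_equal(d12, as.integer(
      phangorn::RF.dist(trees[[1]], trees[[2]])))
  }
})

test_that("group monophyly is detected and broken by a single swap", {
  tr <- read_newick(paste0(
    "(((a1,a2),a3),((b1,b2),b3),(((c1,c2),(d1,d2)),((e1,e2),(f1,f2))));"))
  groups <- c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B", b3 = "B",
              c1 = "C", c2 = "C", d1 = "D", d2 = "D", e1 = "E", e2 = "E",
              f1 = "F", f2 = "F")
  res <- assess_group_monophyly(tr, groups)
  expect_equal(res$n_monophyletic, 6L)

  # swap one taxon between groups C and D
  groups2 <- groups
  groups2["c2"] <- "D"
  groups2["d1"] <- "C"
  res2 <- assess_group_monophyly(tr, groups2)
  tab <- res2$per_group
  expect_false(tab$monophyletic[tab$group == "C"])
  expect_false(tab$monophyletic[tab$group == "D"])
  expect_true(all(tab$monophyletic[!tab$group %in% c("C", "D")]))

  # singleton group: trivially monophyletic, flagged
  res3 <- assess_group_monophyly(tr, c(a1 = "solo"))
  expect_true(res3$per_group$trivial[1])
  expect_true(res3$per_group$monophyletic[1])

  expect_error(assess_group_monophyly(tr, c(zz = "Z")), "absent")
})

test_that("monophyly support reports the edge's bootstrap value", {
  tr <- read_newick("(((a1:1,a2:1)88:1,b1:1)60:1,(c1:1,c2:1)95:1,d1:1);")
  res <- assess_group_monophyly(
    tr, c(a1 = "A", a2 = "A", c1 = "C", c2 = "C", b1 = "B", d1 = "D"))
  tab <- res$per_group
  expect_equal(tab$support[tab$group == "A"], 88)
  expect_equal(tab$support[tab$group == "C"], 95)
})
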