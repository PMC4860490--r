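# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# Small synthetic cohort: 6 genomes, short genes, quick to mine.
small_sim <- function() {
  memo("small_sim", function() {
    tr <- simulate_tree(6, 1, seed = 11)
    cfg <- sim_config(n_taxa = 6,
                      marker_lengths_aa = c(pgm = 60, pgi = 55, fba = 50,
                                            tpi = 40, gap = 45, pgk = 50,
                                            gpm = 35, eno = 55, pyk = 60),
                      len_16s = 300, genome_length = 8000, rng_seed = 11)
    evolve_genomes(tr, cfg)
  })
}

small_db <- function() {
  memo("small_db", function() reference_db_from_sim(small_sim(), 4))
}

# mined small cohort (concatenations, 16S, reports), built once
small_mined <- function() {
  memo("small_mined", function()
    mine_cohort(small_sim()$genomes, small_db(), pipeline_config()))
}

# Full-scale parameter-recovery run: markers at their realistic lengths
# (~3,350 aa concatenated) evolved on a fixed, well-resolved 8-taxon tree,
# then pushed through the whole pipeline. Built once; reused by the
# acceptance checks.
recovery_tree <- function() {
  read_newick(paste0(
    "((T001:0.15,T002:0.12):0.08,(T003:0.10,T004:0.14):0.10,",
    "((T005:0.12,T006:0.10):0.09,(T007:0.11,T008:0.13):0.07):0.06);"))
}

recovery_run <- function() {
  memo("recovery_run", function() {
    cfg <- sim_config(n_taxa = 8, genome_length = 30000, rng_seed = 5)
    sim <- evolve_genomes(recovery_tree(), cfg)
    db <- reference_db_from_sim(sim, 4)
    config <- pipeline_config(n_bootstrap = 100, rng_seed = 5)
    res <- run_pipeline(sim$genomes, db, config,
                        groups = groups_from_tree(sim$tree, 4))
    list(sim = sim, db = db, config = config, res = res)
  })
}
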