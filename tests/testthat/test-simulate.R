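test_that("simulated genomes tile genes with intergenic gaps, reproducibly", {
  cfg <- sim_config(genome_length = 100000, n_genes = 80, seed = 3)
  gf <- simulate_genome_and_features(cfg)
  expect_equal(gf$genome$length, 100000L)
  expect_equal(sum(gf$features$kind == "gene"), 80L)
  expect_true(all(gf$features$end <= 100000L))
  uni <- build_feature_universe(gf$features, gf$genome)
  expect_gte(sum(uni$kind == "intergenic"), 1L)

  gf2 <- simulate_genome_and_features(cfg)
  expect_identical(gf$genome$sequence, gf2$genome$sequence)
  expect_identical(as.data.frame(gf$features), as.data.frame(gf2$features))

  one <- simulate_genome_and_features(
    sim_config(genome_length = 5000, n_genes = 1, seed = 4))
  expect_equal(nrow(one$features), 1L)
  u1 <- build_feature_universe(one$features, one$genome)
  expect_lte(sum(u1$kind == "intergenic"), 2L)
})

test_that("mutant pools hit the target density with unique sites", {
  cfg <- sim_config(genome_length = 90000, n_genes = 50,
                    n_insertions = 5000, seed = 5)
  gf <- simulate_genome_and_features(cfg)
  pool <- simulate_mutant_pool(cfg, gf$genome)
  expect_equal(nrow(pool), 5000L)
  expect_false(anyDuplicated(paste(pool$position, pool$strand)) > 0)
  spacing <- mean_insertion_spacing(90000, nrow(pool))
  expect_equal(spacing, 18, tolerance = 0.1)
  expect_equal(sum(pool$abundance), 1, tolerance = 1e-12)

  empty <- simulate_mutant_pool(
    sim_config(genome_length = 90000, n_insertions = 0, seed = 5),
    gf$genome)
  expect_equal(nrow(empty), 0L)
})

test_that("quantile gating splits 1000 cells exactly 50/50/900", {
  cfg <- sim_config(genome_length = 10000, n_genes = 5,
                    n_insertions = 500, cells_sorted = 1000, seed = 6)
  gf <- simulate_genome_and_features(cfg)
  pool <- simulate_mutant_pool(cfg, gf$genome)
  bins <- sort_pool(pool, rep(1, nrow(pool)), cfg, replicate = 1)
  expect_equal(sum(bins$low), 50L)
  expect_equal(sum(bins$high), 50L)
  expect_equal(sum(bins$depleted), 900L)
})

test_that("a strong repressor feature enriches in the high bin", {
  cfg <- sim_config(genome_length = 50000, n_genes = 25,
                    cells_sorted = 50000, seed = 7)
  gf <- simulate_genome_and_features(cfg)
  pool <- simulate_mutant_pool(cfg, gf$genome)
  # plant a 10x repressor on one gene covering ~1/25 of the genome
  target <- gf$features$feature_id[10]
  eff_map <- c(10)
  names(eff_map) <- target
  eff <- sortnscreen:::site_effects(pool, gf$features, eff_map)
  hit_sites <- eff > 1
  expect_gt(sum(hit_sites), 0)
  bins <- sort_pool(pool, eff, cfg, replicate = 1)
  pool_frac <- sum(pool$abundance[hit_sites])
  high_frac <- sum(bins$high[hit_sites]) / sum(bins$high)
  dep_frac <- sum(bins$depleted[hit_sites]) / sum(bins$depleted)
  expect_gt(high_frac, pool_frac)   # monotone enrichment
  expect_lt(dep_frac, pool_frac)
})

test_that("neutral pools sort exchangeably across bins", {
  cfg <- sim_config(genome_length = 20000, n_genes = 10,
                    n_insertions = 40, cells_sorted = 200000, seed = 8)
  gf <- simulate_genome_and_features(cfg)
  pool <- simulate_mutant_pool(cfg, gf$genome)
  bins <- sort_pool(pool, rep(1, nrow(pool)), cfg, replicate = 1)
  # each site's frequency in each bin tracks its pool abundance
  for (b in names(bins)) {
    frac <- bins[[b]] / sum(bins[[b]])
    expect_gt(cor(frac, pool$abundance), 0.95)
  }
})

test_that("sequencing respects subsampling bounds and depth monotonicity", {
  cfg <- sim_config(genome_length = 30000, n_genes = 15,
                    cells_sorted = 30000, reads_per_sample = 800, seed = 9)
  gf <- simulate_genome_and_features(cfg)
  pool <- simulate_mutant_pool(cfg, gf$genome)
  bins <- sort_pool(pool, rep(1, nrow(pool)), cfg, replicate = 1)
  prof <- sequence_bin(bins$depleted, pool, cfg, gf$genome, "d1", 50L)
  sites <- profile_to_sites(prof)
  expect_lte(nrow(sites), nrow(pool))
  expect_equal(sum(sites$reads), 800L)

  # deeper sequencing recovers at least as many unique sites (paired seeds)
  deep_cfg <- cfg
  deep_cfg$reads_per_sample <- 8000L
  deeper <- vapply(1:5, function(k) {
    a <- sequence_bin(bins$depleted, pool, cfg, gf$genome, "a", 60L + k)
    b <- sequence_bin(bins$depleted, pool, deep_cfg, gf$genome, "b", 60L + k)
    nrow(profile_to_sites(b)) - nrow(profile_to_sites(a))
  }, numeric(1))
  expect_true(all(deeper >= 0))

  expect_warning(
    empty <- sequence_bin(integer(nrow(pool)), pool, cfg, gf$genome,
                          "e", 70L),
    "empty bin")
  expect_equal(sum(empty$forward) + sum(empty$reverse), 0L)
})

test_that("whole screens are bit-deterministic under a fixed seed", {
  cfg <- sim_config(genome_length = 20000, n_genes = 12,
                    cells_sorted = 5000, reads_per_sample = 500,
                    n_replicates = 2, n_repressors = 2, seed = 12)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_screen(cfg, dir = d1)
  simulate_screen(cfg, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("planted effects land in the truth set with the right direction", {
  cfg <- sim_config(genome_length = 50000, n_genes = 40,
                    cells_sorted = 2000, reads_per_sample = 300,
                    n_replicates = 1, n_repressors = 3, n_activators = 2,
                    seed = 13)
  sim <- simulate_screen(cfg)
  expect_equal(sum(sim$truth$direction == "repressor"), 3L)
  expect_equal(sum(sim$truth$direction == "activator"), 2L)
  expect_true(all(sim$truth$feature_id %in% sim$features$feature_id))
  expect_true(all(sim$truth$effect[sim$truth$direction == "repressor"] > 1))
  expect_equal(names(sim$profiles), sim$sheet$sample_id)
})
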