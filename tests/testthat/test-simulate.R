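test_that("identical seeds reproduce the simulation byte-for-byte", {
  cfg <- sim_config(n_demes = 2, deme_N = 30, n_chrom = 2,
    loci_per_chrom = 25, burnin_gens = 10, sample_n = 10, seed = 3,
    hatchery = list(list(target_deme = 2, source_deme = 1,
      broodstock_n = 8, n_seasons = 2, offspring_per_season = 30,
      sweepstakes_shape = 1)))
  a <- simulate_metapop(cfg)
  b <- simulate_metapop(cfg)
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  expect_identical(a$truth$true_ne, b$truth$true_ne)
  expect_identical(a$env, b$env)
})

test_that("drift alone (m = 0, s = 0) builds divergence of the expected
           order between two closed demes", {
  # E[FST] ~ t/(2N) for t << N: 20 generations at N = 200 -> ~0.05
  fsts <- vapply(1:3, function(r) {
    sim <- simulate_metapop(sim_config(
      n_demes = 2, deme_N = 200, n_chrom = 5, loci_per_chrom = 60,
      mig_rate = 0, n_adaptive = 0, sel_coeff = 0, burnin_gens = 20,
      sample_n = 50, free_recomb = TRUE, seed = 30 + r
    ))
    g <- screen_maf(sim$genotypes)
    pairwise_fst(g)["D1", "D2"]
  }, numeric(1))
  expect_true(all(fsts > 0))
  expect_true(abs(mean(fsts) - 0.05) < 0.04)
})

test_that("without selection the adaptive-flagged loci are statistically
           indistinguishable from neutral loci", {
  # s = 0 but adaptive indices still drawn: their FST distribution must
  # match the neutral loci (KS test on pooled replicates)
  adaptive_fst <- neutral_fst <- numeric(0)
  for (r in 1:3) {
    sim <- simulate_metapop(sim_config(
      n_demes = 4, deme_N = 50, n_chrom = 5, loci_per_chrom = 60,
      mig_rate = 0.05, n_adaptive = 40, sel_coeff = 0, burnin_gens = 40,
      sample_n = 25, free_recomb = TRUE, seed = 50 + r
    ))
    g <- screen_maf(sim$genotypes)
    wt <- reefgen:::wc_locus_table(g)
    fst <- wt$comp[, "a"] / rowSums(wt$comp)
    isad <- g$loci$id %in% sim$truth$adaptive_loci$id
    adaptive_fst <- c(adaptive_fst, fst[isad & !is.na(fst)])
    neutral_fst <- c(neutral_fst, fst[!isad & !is.na(fst)])
  }
  ks <- suppressWarnings(stats::ks.test(adaptive_fst, neutral_fst))
  expect_gt(ks$p.value, 0.01)
})

test_that("ideal-reproduction planting limit preserves source
           heterozygosity", {
  # sweepstakes_shape = Inf with broodstock_n = deme_N: equal family
  # sizes from the whole source deme
  sim <- simulate_metapop(sim_config(
    n_demes = 2, deme_N = 100, n_chrom = 4, loci_per_chrom = 60,
    mig_rate = 0, n_adaptive = 0, sel_coeff = 0, burnin_gens = 20,
    sample_n = 60, free_recomb = TRUE, seed = 71,
    hatchery = list(list(target_deme = 2, source_deme = 1,
      broodstock_n = 100, n_seasons = 1, offspring_per_season = 200,
      sweepstakes_shape = Inf))
  ))
  he_src <- het_exp(sim$genotypes, "D1")
  he_planted <- het_exp(sim$genotypes, "D2")
  expect_lt(abs(he_planted - he_src), 0.02)
})

test_that("heterozygosity decays at 1 - 1/(2N) per generation in a
           closed deme", {
  # expectation check: He after t generations ~ He0 (1 - 1/(2N))^t
  N <- 30; t_gens <- 15
  ratios <- vapply(1:20, function(r) {
    sim <- simulate_metapop(sim_config(
      n_demes = 1, deme_N = N, n_chrom = 2, loci_per_chrom = 150,
      mig_rate = 0, n_adaptive = 0, sel_coeff = 0, burnin_gens = t_gens,
      sample_n = N, free_recomb = TRUE, seed = 100 + r
    ))
    p0 <- sim$truth$init_freq
    he0 <- mean(2 * p0 * (1 - p0))
    p1 <- colMeans(sim$genotypes$dosages, na.rm = TRUE) / 2
    he1 <- mean(2 * p1 * (1 - p1))
    (he1 / he0)^(1 / t_gens)
  }, numeric(1))
  expected <- 1 - 1 / (2 * N)
  expect_lt(abs(mean(ratios) - expected), 3 * stats::sd(ratios) /
    sqrt(length(ratios)) + 0.003)
})

test_that("planted-deme truth Ne tracks the Dirichlet-multinomial family
           law and the planting log is complete", {
  cfg <- sim_config(n_demes = 2, deme_N = 100, n_chrom = 2,
    loci_per_chrom = 30, mig_rate = 0, n_adaptive = 0, sel_coeff = 0,
    burnin_gens = 10, sample_n = 30, free_recomb = TRUE, seed = 13,
    hatchery = list(list(target_deme = 2, source_deme = 1,
      broodstock_n = 20, n_seasons = 3, offspring_per_season = 100,
      sweepstakes_shape = 0.5)))
  sim <- simulate_metapop(cfg)
  expect_equal(length(sim$truth$planting_log), 3)
  nb <- vapply(sim$truth$planting_log, function(x) x$nb_season, numeric(1))
  # sweepstakes (shape 0.5) depresses Nb below the broodstock count
  expect_true(all(nb < 20))
  expect_true(all(nb > 0))
  expect_equal(unname(sim$truth$true_ne["D2"]), sum(nb))
  expect_error(
    sim_config(n_demes = 2, deme_N = 10, hatchery = list(list(
      target_deme = 2, source_deme = 1, broodstock_n = 11, n_seasons = 1,
      offspring_per_season = 10))),
    "broodstock_n"
  )
})

test_that("truth reports round-trip with a verifiable config hash", {
  cfg <- sim_config(n_demes = 2, deme_N = 20, n_chrom = 2,
    loci_per_chrom = 20, burnin_gens = 5, sample_n = 10, seed = 17)
  sim <- simulate_metapop(cfg)
  f <- tempfile(fileext = ".json")
  truth_report(sim$truth, cfg, f)
  tr <- read_truth(f)
  expect_equal(tr$seed, 17)
  expect_identical(tr$config_hash, unname(config_hash(cfg)))
  expect_equal(unlist(tr$true_ne), sim$truth$true_ne)
  expect_equal(tr$adaptive_loci$locus, sim$truth$adaptive_loci$locus)
  # tampering with the embedded config is detected
  x <- jsonlite::read_json(f, simplifyVector = TRUE,
    simplifyDataFrame = FALSE)
  x$config$deme_N <- 999
  f2 <- tempfile(fileext = ".json")
  jsonlite::write_json(x, f2, auto_unbox = TRUE, digits = NA)
  expect_warning(read_truth(f2), "hash")
})

test_that("stepping-stone migration produces isolation by distance", {
  # positive Mantel correlation of FST/(1-FST) vs distance across reps
  hits <- vapply(1:10, function(r) {
    sim <- simulate_metapop(sim_config(
      n_demes = 6, deme_N = 50, n_chrom = 4, loci_per_chrom = 60,
      mig_rate = 0.05, n_adaptive = 0, sel_coeff = 0, burnin_gens = 60,
      sample_n = 20, free_recomb = TRUE, seed = 200 + r
    ))
    g <- screen_maf(sim$genotypes)
    mantel_ibd(pairwise_fst(g), sim$dist, n_perm = 49, seed = r)$r > 0
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
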