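# small in-code fixtures and cached simulations shared across tests

toy_genotypes <- function(dosages, sites = NULL, chrom = NULL, pos = NULL) {
  dosages <- as.matrix(dosages)
  L <- ncol(dosages)
  n <- nrow(dosages)
  if (is.null(sites)) sites <- rep("A", n)
  if (is.null(chrom)) chrom <- rep("chr1", L)
  if (is.null(pos)) pos <- seq_len(L)
  genotype_matrix(
    dosages,
    data.frame(chrom = chrom, pos = pos, id = paste0("L", seq_len(L)),
      stringsAsFactors = FALSE),
    data.frame(id = paste0("i", seq_len(n)), site = sites,
      stringsAsFactors = FALSE)
  )
}

# random genotype matrix in HWE at uniform frequencies
random_genotypes <- function(n, L, sites = NULL, seed = 1,
                             missing_rate = 0) {
  set.seed(seed)
  p <- stats::runif(L, 0.05, 0.95)
  d <- matrix(stats::rbinom(n * L, 2L, rep(p, each = n)), n, L)
  if (missing_rate > 0) d[stats::runif(n * L) < missing_rate] <- NA_integer_
  toy_genotypes(d, sites = sites)
}

sim_cache <- new.env(parent = emptyenv())

cached_sim <- function(key, maker) {
  if (is.null(sim_cache[[key]])) sim_cache[[key]] <- maker()
  sim_cache[[key]]
}

# neutral island-model metapopulation (scan null calibration, FST)
island_sim <- function() cached_sim("island", function() {
  simulate_metapop(sim_config(
    n_demes = 8, deme_N = 50, n_chrom = 10, loci_per_chrom = 150,
    mig_rate = 0.1, migration_model = "island", n_adaptive = 0,
    sel_coeff = 0, burnin_gens = 80, sample_n = 30, free_recomb = TRUE,
    seed = 11
  ))
})

# two-deme strong-selection split (scan power)
selection_sim <- function() cached_sim("selection", function() {
  simulate_metapop(sim_config(
    n_demes = 2, deme_N = 100, n_chrom = 10, loci_per_chrom = 100,
    mig_rate = 0.05, n_adaptive = 50, sel_coeff = 0.3,
    env_gradient = c(8, 28), burnin_gens = 60, sample_n = 50,
    free_recomb = TRUE, seed = 21
  ))
})

# six-deme stepping stone (IBD, structure)
stepping_sim <- function() cached_sim("stepping", function() {
  simulate_metapop(sim_config(
    n_demes = 6, deme_N = 60, n_chrom = 5, loci_per_chrom = 80,
    mig_rate = 0.04, n_adaptive = 0, sel_coeff = 0, burnin_gens = 100,
    sample_n = 25, free_recomb = TRUE, seed = 8
  ))
})

# Independent transcription of the two-population variance-component
# estimator, summing components per allele as the original derivation
# does (the package computes the biallelic shortcut).
brute_wc_theta <- function(d1, d2) {
  num <- den <- 0
  for (l in seq_len(ncol(d1))) {
    x1 <- d1[, l][!is.na(d1[, l])]
    x2 <- d2[, l][!is.na(d2[, l])]
    if (length(x1) < 2 || length(x2) < 2) next
    n <- c(length(x1), length(x2))
    r <- 2
    for (allele in c("alt", "ref")) {
      p <- if (allele == "alt") c(mean(x1) / 2, mean(x2) / 2)
        else c(1 - mean(x1) / 2, 1 - mean(x2) / 2)
      h <- c(mean(x1 == 1), mean(x2 == 1))
      if (all(p == 0) || all(p == 1)) next
      nbar <- mean(n)
      nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
      pbar <- sum(n * p) / sum(n)
      s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n * h) / sum(n)
      a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
        (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
      b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) -
        ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  num / den
}

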