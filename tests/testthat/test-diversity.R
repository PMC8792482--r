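test_that("observed heterozygosity matches hand counts and a brute-force
           oracle", {
  expect_equal(het_obs(toy_genotypes(cbind(c(1, 1, 0, 2))), "A"), 0.5)
  # monomorphic locus contributes 0
  expect_equal(
    het_obs(toy_genotypes(cbind(c(1, 1, 0, 2), c(0, 0, 0, 0))), "A"), 0.25
  )
  g <- random_genotypes(30, 100, seed = 9, missing_rate = 0.05)
  brute <- mean(apply(g$dosages, 2, function(x) {
    x <- x[!is.na(x)]
    sum(x == 1) / length(x)
  }), na.rm = TRUE)
  expect_equal(het_obs(g, "A"), brute, tolerance = 1e-12)
})

test_that("expected heterozygosity uses the unbiased small-sample
           correction and is symmetric in alleles", {
  # p = 0.5, n = 2: (2n/(2n-1)) (1 - p^2 - q^2) = (4/3)(0.5)
  expect_equal(het_exp(toy_genotypes(cbind(c(0, 2))), "A"), 2 / 3,
    tolerance = 1e-12)
  expect_equal(het_exp(toy_genotypes(cbind(c(2, 2, 2))), "A"), 0)
  g <- random_genotypes(25, 60, seed = 10)
  flipped <- toy_genotypes(2L - g$dosages)
  expect_equal(het_exp(g, "A"), het_exp(flipped, "A"), tolerance = 1e-12)
})

test_that("rarefied allelic richness matches exhaustive subsample
           enumeration", {
  # 2n = 6 genes, rarefy to g* = 4: enumerate all C(6,4) subsets
  d <- cbind(c(0, 1, 2), c(1, 1, 0), c(2, 2, 2))
  g <- toy_genotypes(d)
  enumerate_ar <- function(genes, gstar) {
    combos <- utils::combn(length(genes), gstar)
    mean(apply(combos, 2, function(k) length(unique(genes[k]))))
  }
  expected <- mean(apply(d, 2, function(x) {
    genes <- c(rep(0, sum(2 - x)), rep(1, sum(x)))
    enumerate_ar(genes, 4)
  }))
  expect_equal(unname(allelic_richness(g, rarefy_to = 4)["A"]), expected,
    tolerance = 1e-12)
  # monomorphic locus -> 1; saturation as g* -> 2n
  g1 <- toy_genotypes(cbind(c(0, 0, 0)))
  expect_equal(unname(allelic_richness(g1, rarefy_to = 4)["A"]), 1)
  g2 <- toy_genotypes(cbind(c(0, 1, 2)))
  expect_equal(unname(allelic_richness(g2, rarefy_to = 6)["A"]), 2)
  expect_error(allelic_richness(g2, rarefy_to = 1), ">= 2")
})

test_that("FIS sign, determinism, and bootstrap coverage behave as a
           within-site inbreeding coefficient should", {
  # all heterozygotes: strong heterozygote excess
  g <- toy_genotypes(matrix(1L, 6, 20))
  expect_lt(fis(g, "A", n_boot = 50)$fis, 0)
  # fixed seed reproduces the interval exactly
  g2 <- random_genotypes(20, 100, seed = 12)
  a <- fis(g2, "A", n_boot = 200, seed = 5)
  b <- fis(g2, "A", n_boot = 200, seed = 5)
  expect_identical(a, b)
  expect_lte(a$lo, a$fis)
  expect_gte(a$hi, a$fis)
  # Hardy-Weinberg sites: CI covers 0 in most replicates
  covers <- vapply(1:10, function(r) {
    gh <- random_genotypes(40, 2000, seed = 300 + r)
    ci <- fis(gh, "A", n_boot = 200, seed = r)
    ci$lo <= 0 && ci$hi >= 0
  }, logical(1))
  expect_gte(mean(covers), 0.9)
})

test_that("Ritland relatedness matches its single-locus closed form and is
           calibrated on known pedigrees", {
  # x = y = AA at a biallelic locus with p = 0.5 -> r = 2
  g <- toy_genotypes(rbind(2, 2))
  r <- ritland_relatedness(g, "A", freqs = 0.5, min_loci = 1)
  expect_equal(r$r[1, 2], 2)

  un <- simulate_pairs(200, 3000, "unrelated", seed = 2)
  idx <- cbind(seq(1, 399, 2), seq(2, 400, 2))
  r_un <- ritland_relatedness(un$genotypes, "P")
  expect_lt(abs(mean(r_un$r[idx])), 0.02)

  po <- simulate_pairs(200, 3000, "parent_offspring", seed = 3)
  r_po <- ritland_relatedness(po$genotypes, "P")
  expect_lt(abs(mean(r_po$r[idx]) - 0.5), 0.05)

  # symmetry and the minimum joint-loci rule
  expect_equal(r_un$r, t(r_un$r))
  g3 <- toy_genotypes(rbind(c(1, NA, NA), c(1, 1, 1), c(0, 1, 2)))
  r3 <- ritland_relatedness(g3, "A", min_loci = 2)
  expect_true(is.na(r3$r[1, 2]) || !is.na(r3$r[2, 3]))
})

test_that("sMLH is centered at 1 and scales with heterozygous share", {
  g <- toy_genotypes(matrix(rep(c(0L, 1L, 2L, 1L), each = 4), 4, 4))
  expect_equal(unname(smlh(g)), rep(1, 4))
  g2 <- random_genotypes(40, 300, seed = 14)
  expect_equal(mean(smlh(g2)), 1, tolerance = 1e-12)
  # doubling an individual's het share doubles its sMLH given the same
  # denominator loci
  s <- smlh(g2)
  hets <- rowMeans(g2$dosages == 1)
  expect_equal(unname(s / hets), rep(unname(s[1] / hets[1]), 40),
    tolerance = 1e-9)
})

test_that("diversity statistics are invariant to individual and locus
           permutations", {
  g <- random_genotypes(20, 80, sites = rep(c("A", "B"), 10), seed = 15)
  set.seed(1)
  gi <- subset_genotypes(g, ind = sample(20))
  expect_equal(het_obs(g, "A"), het_obs(gi, "A"), tolerance = 1e-12)
  expect_equal(het_exp(g, "B"), het_exp(gi, "B"), tolerance = 1e-12)
  expect_equal(allelic_richness(g)[c("A", "B")],
    allelic_richness(gi)[c("A", "B")], tolerance = 1e-12)
  expect_equal(ritland_relatedness(g, "A")$mean,
    ritland_relatedness(gi, "A")$mean, tolerance = 1e-12)
})

test_that("diversity_summary assembles one coherent row per site", {
  sim <- stepping_sim()
  g <- screen_maf(sim$genotypes)
  div <- diversity_summary(g, n_boot = 100, seed = 1)
  expect_equal(div$site, unique(sites_of(g)))
  expect_true(all(div$Ho >= 0 & div$Ho <= 1))
  expect_true(all(div$He >= 0 & div$He <= 1))
  expect_true(all(div$Ar >= 1 & div$Ar <= 2))
  expect_true(all(div$FIS_lo <= div$FIS & div$FIS <= div$FIS_hi))
  # random-mating simulator output: |Ho - He| small
  expect_true(all(abs(div$Ho - div$He) < 0.05))
})
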