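test_that("pairwise r2 equals the squared Pearson correlation and skips
           degenerate pairs", {
  d <- cbind(c(0, 1, 2, 1, 0, 2, 1, 1, 0, 2))
  g <- toy_genotypes(cbind(d, d), chrom = c("chr1", "chr2"), pos = c(1, 1))
  ld <- pairwise_r2(g, min_joint = 5)
  expect_equal(ld$r2, 1)
  expect_false(ld$intra)

  # constant locus -> pair skipped and counted
  g2 <- toy_genotypes(cbind(d, rep(1L, 10)),
    chrom = c("chr1", "chr2"), pos = c(1, 1))
  ld2 <- pairwise_r2(g2, min_joint = 5)
  expect_equal(nrow(ld2), 0)
  expect_equal(attr(ld2, "n_skipped"), 1)

  g3 <- random_genotypes(25, 40, seed = 21, missing_rate = 0.1)
  ld3 <- pairwise_r2(g3, min_joint = 10)
  k <- sample(nrow(ld3), 25)
  direct <- vapply(k, function(row) {
    x <- g3$dosages[, ld3$i[row]]
    y <- g3$dosages[, ld3$j[row]]
    ok <- !is.na(x) & !is.na(y)
    stats::cor(x[ok], y[ok])^2
  }, numeric(1))
  expect_equal(ld3$r2[k], direct, tolerance = 1e-10)
  expect_true(all(ld3$intra == (ld3$chrom == "chr1") |
    is.na(ld3$chrom)))
})

test_that("critical r2 is the squared 95th percentile of root-transformed
           unlinked LD", {
  fake_ld <- function(r2) {
    structure(
      data.frame(i = 1, j = 2, chrom = NA, r2 = r2, dist_bp = NA,
        intra = FALSE, S = 30),
      class = c("ld_result", "data.frame")
    )
  }
  expect_equal(critical_r2(fake_ld(rep(0.03, 200))), 0.03)
  # closed form: r2 ~ U(0, 0.04) -> sqrt(r2) = 0.2 sqrt(U), whose 95th
  # percentile is 0.2 sqrt(0.95); squared: 0.04 * 0.95 = 0.038
  set.seed(4)
  mc <- critical_r2(fake_ld(stats::runif(2e5, 0, 0.04)))
  expect_lt(abs(mc - 0.038), 0.002)
  x <- stats::runif(500, 0.01, 0.09)
  expect_true(critical_r2(fake_ld(x)) >= min(x) &&
    critical_r2(fake_ld(x)) <= max(x))
  expect_error(critical_r2(fake_ld(rep(0.01, 50))), ">= 100")
})

make_decay_ld <- function(n_pairs = 4000, noise = 0, seed = 1) {
  set.seed(seed)
  d <- stats::runif(n_pairs, 0, 3000)
  r2 <- pmin(1, pmax(0, exp(-d / 500) + stats::rnorm(n_pairs, 0, noise)))
  structure(
    data.frame(i = 1, j = 2, chrom = "chr1", r2 = r2, dist_bp = d,
      intra = TRUE, S = 30),
    class = c("ld_result", "data.frame")
  )
}

test_that("LOESS decay recovers a known curve and degenerates sensibly", {
  cv <- loess_decay(make_decay_ld(), "chr1", span = 0.3)
  truth <- exp(-cv$dist / 500)
  interior <- cv$dist > 100 & cv$dist < 2500
  expect_lt(max(abs(cv$r2[interior] - truth[interior])), 0.02)

  const <- make_decay_ld()
  const$r2 <- 0.2
  cvc <- loess_decay(const, "chr1")
  expect_lt(max(abs(cvc$r2 - 0.2)), 1e-6)

  # permutation invariance to pair order
  perm <- make_decay_ld()
  cvp <- loess_decay(perm[sample(nrow(perm)), ], "chr1", span = 0.3)
  cv0 <- loess_decay(perm, "chr1", span = 0.3)
  expect_equal(cvp$r2, cv0$r2, tolerance = 1e-10)

  expect_null(loess_decay(make_decay_ld(n_pairs = 20), "chr1"))
})

test_that("thinning distance is the LOESS/critical crossing, within one
           grid step of the analytic value", {
  ld <- make_decay_ld(n_pairs = 6000, noise = 0.005, seed = 2)
  crit <- exp(-1)   # crossing of exp(-d/500) at d = 500
  plan <- thinning_plan(ld, crit, span = 0.3)
  step <- diff(loess_decay(ld, "chr1", span = 0.3)$dist[1:2])
  expect_lt(abs(plan$per_chrom[["chr1"]] - 500), step + 1e-9)

  # curve entirely below the critical value -> no thinning
  plan2 <- thinning_plan(ld, crit = 1.5)
  expect_true(is.na(plan2$per_chrom[["chr1"]]))
})

test_that("greedy thinning keeps the leftmost locus of each window and
           never leaves close pairs", {
  g <- toy_genotypes(matrix(0:2, 3, 3), pos = c(1, 100, 260))
  plan <- structure(list(critical_r2 = 0.1,
    per_chrom = c(chr1 = 250)), class = "thinning_plan")
  gt <- thin(g, plan)
  expect_equal(gt$loci$pos, c(1, 260))

  # zero / absent distance leaves the input untouched
  expect_equal(n_loci(thin(g, structure(list(critical_r2 = 0.1,
    per_chrom = c(chr1 = NA_real_)), class = "thinning_plan"))), 3)
  expect_equal(n_loci(thin(g, 0)), 3)

  sim <- stepping_sim()
  gs <- screen_maf(sim$genotypes)
  gthin <- thin(gs, 5e5)
  for (ch in unique(gthin$loci$chrom)) {
    p <- gthin$loci$pos[gthin$loci$chrom == ch]
    if (length(p) > 1) expect_true(all(diff(p) >= 5e5))
  }
})

test_that("the LD Ne estimator recovers simulated Ne and responds to
           hidden structure in the known direction", {
  # recovery is exercised in depth by the acceptance suite; here a single
  # replicate must land within a loose band around truth
  sim <- simulate_metapop(sim_config(
    n_demes = 1, deme_N = 100, n_chrom = 20, loci_per_chrom = 100,
    mig_rate = 0, n_adaptive = 0, sel_coeff = 0, burnin_gens = 50,
    sample_n = 50, free_recomb = TRUE, seed = 101
  ))
  est <- ld_ne(sim$genotypes, "D1", ci = FALSE)
  expect_gt(est$ne, 50)
  expect_lt(est$ne, 200)

  # pooling two diverged demes (Wahlund) biases Ne downward
  two <- simulate_metapop(sim_config(
    n_demes = 2, deme_N = 100, n_chrom = 10, loci_per_chrom = 100,
    mig_rate = 0.005, n_adaptive = 0, sel_coeff = 0, burnin_gens = 80,
    sample_n = 25, free_recomb = TRUE, seed = 102
  ))
  single <- ld_ne(two$genotypes, "D1", ci = FALSE)
  pooled <- ld_ne(two$genotypes, site = NULL, ci = FALSE)
  expect_lt(pooled$ne, single$ne)
})

test_that("jackknife intervals are deterministic and the no-LD null gives
           unbounded upper limits", {
  g <- random_genotypes(30, 60, seed = 33)
  a <- ld_ne(g, "A", seed = 2)
  b <- ld_ne(g, "A", seed = 2)
  expect_identical(a[c("ne", "lo", "hi", "r2")], b[c("ne", "lo", "hi", "r2")])
  expect_lte(a$lo, ifelse(is.finite(a$ne), a$ne, a$lo))

  # independent loci, no drift LD: upper CI hits infinity in most reps
  inf_hits <- vapply(1:6, function(r) {
    gh <- random_genotypes(40, 150, seed = 400 + r)
    est <- ld_ne(gh, "A", seed = r)
    !is.finite(est$hi)
  }, logical(1))
  expect_gte(mean(inf_hits), 0.5)
})

test_that("the life-history adjustment follows its published form", {
  raw <- structure(list(ne = 100, lo = 50, hi = 300, r2 = 0.01,
    r2_drift = 0.003, S = 49, n_pairs = 1000, n_loci = 100, pcrit = 0.02,
    adjusted = FALSE, life_history = NULL), class = "ne_estimate")
  # AL = alpha degenerates to the intercept alone
  eq <- adjust_nb(raw, AL = 2.0001, alpha = 2)
  expect_equal(eq$nb_adj, 100 / 1.103, tolerance = 1e-3)
  # AL = 15, alpha = 2 (eastern-oyster life history)
  adj <- adjust_nb(raw, AL = 15, alpha = 2, CVf = 0.65)
  den <- 1.103 - 0.245 * log10(7.5)
  expect_equal(adj$nb_adj, 100 / den, tolerance = 1e-12)
  expect_equal(adj$ne, 100 / den / (0.485 + 0.758 * log10(7.5)),
    tolerance = 1e-12)
  expect_equal(adj$lo / raw$lo, adj$hi / raw$hi, tolerance = 1e-12)
  # monotone in the input estimate
  raw2 <- raw; raw2$ne <- 200
  expect_gt(adjust_nb(raw2, 15, 2)$ne, adj$ne)
  expect_error(adjust_nb(raw, AL = 2, alpha = 2), "AL > alpha")
})
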