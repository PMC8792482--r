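test_that("the VIF screen matches hand-computed inflation factors and
           drops exactly one of a duplicated pair", {
  set.seed(9)
  X <- data.frame(a = stats::rnorm(30), b = stats::rnorm(30))
  X$c <- 0.8 * X$a + 0.3 * X$b + stats::rnorm(30, 0, 0.3)
  hand_vif <- vapply(1:3, function(j) {
    1 / (1 - summary(stats::lm(X[[j]] ~ ., data = X[-j]))$r.squared)
  }, numeric(1))
  scr <- vif_screen(X, max_vif = 1e6)   # no dropping, just the VIFs
  expect_equal(unname(attr(scr, "vif")), unname(hand_vif),
    tolerance = 1e-8)

  # orthogonal variables all kept with VIF ~ 1
  O <- data.frame(x = c(1, -1, 1, -1, 1, -1), y = c(1, 1, -1, -1, 1, 1) -
    1 / 3)
  scr2 <- vif_screen(O, max_vif = 10)
  expect_equal(ncol(scr2), 2)
  expect_true(all(attr(scr2, "vif") < 1.5))

  D <- data.frame(u = stats::rnorm(20), v = stats::rnorm(20))
  D$w <- D$u * 2
  scr3 <- vif_screen(D, max_vif = 10)
  expect_equal(length(attr(scr3, "dropped")), 1)
  expect_equal(ncol(scr3), 2)
})

test_that("rda_fit agrees with an independent RDA implementation on
           eigenvalues, R2 and partial constrained variance", {
  set.seed(2)
  Y <- matrix(stats::rnorm(30 * 50), 30, 50)
  X <- matrix(stats::rnorm(30 * 3), 30, 3)
  colnames(X) <- c("a", "b", "c")
  C <- matrix(stats::rnorm(30 * 2), 30, 2)
  colnames(C) <- c("p1", "p2")

  f <- rda_fit(Y, X, n_perm = 0)
  v <- vegan::rda(Y ~ a + b + c, data = as.data.frame(X))
  expect_equal(f$R2, unname(vegan::RsquareAdj(v)$r.squared),
    tolerance = 1e-10)
  expect_equal(f$R2_adj, unname(vegan::RsquareAdj(v)$adj.r.squared),
    tolerance = 1e-10)
  expect_equal(f$eig[1:3], unname(v$CCA$eig[1:3]), tolerance = 1e-8)

  fp <- rda_fit(Y, X, condition = C, n_perm = 0)
  vp <- vegan::rda(Y ~ a + b + c + Condition(p1 + p2),
    data = data.frame(X, C))
  expect_equal(fp$ss_fit, sum(vp$CCA$eig) * (30 - 1), tolerance = 1e-8)
})

test_that("the Ezekiel adjustment reproduces the published pairing and
           the exact-fit/degenerate cases behave", {
  expect_lt(abs(adj_r2(0.0234, 478, 6) - 0.011), 5e-5)

  set.seed(3)
  x <- stats::rnorm(40)
  Y <- outer(x, stats::rnorm(25))
  f <- rda_fit(Y, cbind(x = x), n_perm = 99, seed = 1)
  expect_equal(f$R2, 1, tolerance = 1e-10)
  expect_equal(f$eig[1] / sum(f$eig), 1, tolerance = 1e-10)
  expect_equal(f$anova$p, 1 / 100)
  expect_error(rda_fit(Y[1:3, ], matrix(stats::rnorm(9), 3, 3)),
    "df")
})

test_that("the permutation test is valid under the null and p-values
           respect their attainable range", {
  set.seed(4)
  calm <- vapply(1:10, function(r) {
    Y <- matrix(stats::rnorm(25 * 40), 25, 40)
    X <- matrix(stats::rnorm(25 * 2), 25, 2)
    rda_fit(Y, X, n_perm = 99, seed = r)$anova$p
  }, numeric(1))
  expect_gte(mean(calm >= 0.05), 0.9)
  expect_true(all(calm >= 1 / 100 & calm <= 1))
})

test_that("with a single binary predictor the first-axis SNP loadings are
           the per-locus group mean contrasts", {
  g <- random_genotypes(40, 200, sites = rep(c("A", "B"), 20), seed = 91)
  x <- as.numeric(sites_of(g) == "B")
  f <- rda_fit(g, cbind(x = x), n_perm = 0)
  diffs <- colMeans(g$dosages[x == 1, ]) - colMeans(g$dosages[x == 0, ])
  expect_gt(abs(stats::cor(f$snp_loadings[, 1], diffs)), 0.999)
})

test_that("GEA outliers: a SNP at the robust center is not an outlier,
           the flag set ignores SNP order, and the null lambda is near 1", {
  g <- random_genotypes(60, 600, sites = rep(c("A", "B", "C"), 20),
    seed = 92)
  env <- cbind(
    e1 = stats::rnorm(60), e2 = stats::rnorm(60), e3 = stats::rnorm(60)
  )
  f <- rda_fit(g, env, n_perm = 0)
  go <- gea_outliers(f, n_axes = 2, seed = 1)
  expect_gte(attr(go, "lambda"), 0.7)
  expect_lte(attr(go, "lambda"), 1.3)
  center_snp <- which.min(go$D2)
  expect_gt(go$p[center_snp], 0.5)

  set.seed(5)
  gi <- subset_genotypes(g, loci = sample(n_loci(g)))
  goi <- gea_outliers(rda_fit(gi, env, n_perm = 0), n_axes = 2, seed = 1)
  expect_equal(sort(go$id[go$flagged]), sort(goi$id[goi$flagged]))
  expect_error(gea_outliers(f, n_axes = 10), "exceeds")
})

test_that("PCNM axes reproduce principal-coordinate geometry", {
  d3 <- matrix(10, 3, 3); diag(d3) <- 0
  dimnames(d3) <- list(c("A", "B", "C"), c("A", "B", "C"))
  p3 <- pcnm_axes(d3)
  ev <- attr(p3, "values")
  expect_equal(ev[1], ev[2], tolerance = 1e-8)   # symmetric pair

  dl <- abs(outer(1:8, 1:8, "-")) * 5
  dimnames(dl) <- list(paste0("S", 1:8), paste0("S", 1:8))
  pl <- pcnm_axes(dl)
  # broad-scale axis tracks position along the transect
  expect_gt(abs(stats::cor(pl[, 1], 1:8)), 0.7)
  # orthonormal eigenvectors
  expect_equal(crossprod(pl), diag(ncol(pl)), tolerance = 1e-8,
    ignore_attr = TRUE)
  expect_error(pcnm_axes(d3[1:2, 1:2]), ">= 3")
})

test_that("variance partitioning: fractions are additive and confounded
           predictors leave no unique fractions", {
  g <- random_genotypes(45, 300, sites = rep(c("A", "B", "C"), 15),
    seed = 93)
  set.seed(6)
  E <- cbind(e = stats::rnorm(45), f = stats::rnorm(45))
  S <- cbind(s1 = stats::rnorm(45), s2 = stats::rnorm(45))
  vp <- variance_partition(g, E, S, n_perm = 49, seed = 1)
  expect_equal(vp$R2[vp$fraction == "joint"],
    vp$R2[vp$fraction == "full"] - vp$R2[vp$fraction == "env_unique"] -
      vp$R2[vp$fraction == "space_unique"], tolerance = 1e-10)

  # identical matrices: all shared, nothing unique
  vp2 <- variance_partition(g, E, E + 0, n_perm = 0)
  expect_lt(vp2$R2[vp2$fraction == "env_unique"], 1e-8)
  expect_lt(vp2$R2[vp2$fraction == "space_unique"], 1e-8)
  expect_equal(vp2$R2[vp2$fraction == "joint"],
    vp2$R2[vp2$fraction == "full"], tolerance = 1e-8)
})

test_that("space-only structure attributes no unique variance to a noise
           environment", {
  sim <- stepping_sim()
  g <- screen_maf(sim$genotypes)
  pc <- pcnm_axes(sim$dist)
  S <- broadcast_to_ind(
    data.frame(site = rownames(pc), pc[, 1:2]), sites_of(g)
  )
  hits <- vapply(1:5, function(r) {
    set.seed(700 + r)
    E <- cbind(noise = stats::rnorm(nrow(sim$env))[
      match(sites_of(g), sim$env$site)])
    vp <- variance_partition(g, E, S, n_perm = 99,
      blocks = sites_of(g), seed = r)
    vp$p[vp$fraction == "env_unique"] > 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
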