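#' Pairwise Weir-Cockerham FST between sites
#'
#' For each site pair, per-locus variance components a (among-population),
#' b (among-individual), c (within-individual) from the two-population
#' Weir-Cockerham formulas with unequal sample sizes; the pair's theta is
#' the ratio of sums over loci (the recommended multi-locus combination),
#' skipping loci monomorphic in the pair. Small negative values are
#' reported as computed.
#'
#' @param g a \code{\link{genotype_matrix}}
#' @param sites site labels to include; default all.
#' @return symmetric matrix of class \code{fst_matrix}, zero diagonal.
#' @export
pairwise_fst <- function(g, sites = NULL) {
  if (is.null(sites)) sites <- unique(sites_of(g))
  r <- length(sites)
  if (r < 2) stop("pairwise_fst needs >= 2 sites")
  stats_by_site <- lapply(sites, function(s) {
    d <- site_dosages(g, s)
    n <- colSums(!is.na(d))
    if (all(n == 0)) stop("site with all-missing loci: ", s)
    list(
      n = n, p = colMeans(d, na.rm = TRUE) / 2,
      h = colMeans(d == 1L, na.rm = TRUE)
    )
  })
  theta <- matrix(0, r, r, dimnames = list(sites, sites))
  for (i in seq_len(r - 1)) {
    for (j in (i + 1):r) {
      A <- stats_by_site[[i]]; B <- stats_by_site[[j]]
      ok <- A$n >= 2 & B$n >= 2
      poly <- ok & !((A$p == 0 & B$p == 0) | (A$p == 1 & B$p == 1)) &
        !is.na(A$p) & !is.na(B$p)
      sa <- sb <- sc <- 0
      for (l in which(poly)) {
        cp <- wc_components(
          c(A$n[l], B$n[l]), c(A$p[l], B$p[l]), c(A$h[l], B$h[l])
        )
        sa <- sa + cp[1]; sb <- sb + cp[2]; sc <- sc + cp[3]
      }
      theta[i, j] <- theta[j, i] <-
        if (sa + sb + sc == 0) NA_real_ else sa / (sa + sb + sc)
    }
  }
  class(theta) <- c("fst_matrix", class(theta))
  theta
}

#' Mantel test of isolation by distance
#'
#' Pairwise FST linearized as FST/(1-FST) against water distance; the
#' Mantel statistic is the Pearson correlation of the upper triangles, with
#' a one-sided permutation p-value from permuting site labels of one
#' matrix. Negative theta is floored at 0 before linearization (the
#' transform distorts below 0); an OLS adjusted R-squared on the distance
#' pairs is reported alongside the squared Mantel correlation.
#'
#' @param fst an FST matrix (sites x sites).
#' @param dist a water-distance matrix over the same sites (any order).
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @return list: \code{r}, \code{R2} (= r^2), \code{R2_adj_ols}, \code{p},
#'   \code{n_perm}.
#' @export
mantel_ibd <- function(fst, dist, n_perm = 999, seed = 1) {
  sites <- rownames(fst)
  if (is.null(sites) || !all(sites %in% rownames(dist)))
    stop("mantel_ibd: site sets do not match")
  if (length(sites) < 4) stop("mantel_ibd needs >= 4 sites")
  dist <- dist[sites, sites]
  th <- pmax(unclass(fst), 0)
  if (any(th == 1)) {
    warning("FST = 1 pair(s) excluded from Mantel linearization")
    th[th == 1] <- NA
  }
  lin <- th / (1 - th)
  ut <- upper.tri(lin)
  x <- lin[ut]; y <- dist[ut]
  ok <- !is.na(x)
  r_obs <- stats::cor(x[ok], y[ok])
  set.seed(seed)
  n <- length(sites)
  perm_r <- vapply(seq_len(n_perm), function(i) {
    k <- sample.int(n)
    lp <- lin[k, k]
    xo <- lp[ut]
    stats::cor(xo[ok], y[ok])
  }, numeric(1))
  p <- (1 + sum(perm_r >= r_obs)) / (n_perm + 1)
  fit <- stats::lm(x[ok] ~ y[ok])
  list(
    r = r_obs, R2 = r_obs^2,
    # suppressed: lm warns on exactly collinear (perfect-IBD) input
    R2_adj_ols = suppressWarnings(summary(fit)$adj.r.squared),
    p = p, n_perm = n_perm
  )
}

# PCA scores of centered, mean-imputed dosages.
pca_scores <- function(g, n_pc) {
  X <- g$dosages
  mu <- colMeans(X, na.rm = TRUE)
  X <- sweep(X, 2, mu, "-")
  X[is.na(X)] <- 0
  sv <- svd(X, nu = min(n_pc, nrow(X) - 1), nv = 0)
  k <- min(n_pc, ncol(sv$u))
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- g$individuals$id
  scores
}

#' Discriminant analysis of principal components with cross-validated
#' PC selection
#'
#' PCA of centered (mean-imputed) dosages; for each candidate number of
#' retained PCs, repeated stratified holdout cross-validation of a linear
#' discriminant on the PC scores estimates assignment success; the PC count
#' maximizing mean success is kept (ties to fewer PCs), refined by a second
#' pass over +/-10 PCs, and the final discriminant functions are fit on all
#' data.
#'
#' @param g a \code{\link{genotype_matrix}}
#' @param groups grouping labels per individual; default the site labels.
#' @param pc_range candidate PC counts; default a coarse grid up to n-2.
#' @param n_xval holdout replicates per candidate.
#' @param holdout fraction held out per group.
#' @param seed RNG seed.
#' @return list of class \code{dapc_result}: \code{n_pcs_retained},
#'   \code{assignments}, \code{posterior}, \code{scores} (discriminant
#'   scores), \code{xval_success}, \code{success_by_npc}.
#' @export
dapc <- function(g, groups = NULL, pc_range = NULL, n_xval = 500,
                 holdout = 0.1, seed = 1) {
  if (is.null(groups)) groups <- sites_of(g)
  groups <- factor(groups)
  n <- n_ind(g)
  small <- names(which(table(groups) < 3))
  if (length(small) > 0)
    warning("group(s) with < 3 members excluded from cross-validation: ",
      paste(small, collapse = ", "))
  if (is.null(pc_range)) {
    hi <- max(2, min(n - 2, 100))
    pc_range <- unique(round(seq(2, hi, length.out = min(10, hi - 1))))
  }
  max_pc <- min(n - 2, max(pc_range))
  scores <- pca_scores(g, max_pc)

  xval_success <- function(npc, reps) {
    ok_groups <- levels(groups)[table(groups) >= 3]
    idx_ok <- which(groups %in% ok_groups)
    succ <- vapply(seq_len(reps), function(rep) {
      hold <- unlist(lapply(ok_groups, function(gr) {
        members <- idx_ok[groups[idx_ok] == gr]
        sample(members, max(1, round(holdout * length(members))))
      }))
      train <- setdiff(idx_ok, hold)
      if (length(unique(groups[train])) < 2) return(NA_real_)
      # lda warns when retained PCs approach the training size; the
      # cross-validation is exactly the guard against that overfit
      fit <- suppressWarnings(MASS::lda(
        scores[train, seq_len(npc), drop = FALSE],
        grouping = droplevels(groups[train])
      ))
      pred <- stats::predict(fit, scores[hold, seq_len(npc), drop = FALSE])
      mean(as.character(pred$class) == as.character(groups[hold]))
    }, numeric(1))
    mean(succ, na.rm = TRUE)
  }

  set.seed(seed)
  pc_range <- pc_range[pc_range <= max_pc & pc_range >= 1]
  succ1 <- vapply(pc_range, xval_success, numeric(1), reps = n_xval)
  best1 <- pc_range[which.max(succ1)]
  refine <- unique(pmax(1, pmin(max_pc, (best1 - 10):(best1 + 10))))
  refine <- setdiff(refine, pc_range)
  succ2 <- if (length(refine)) vapply(refine, xval_success, numeric(1),
    reps = n_xval) else numeric(0)
  all_npc <- c(pc_range, refine)
  all_succ <- c(succ1, succ2)
  ord <- order(all_npc)
  all_npc <- all_npc[ord]; all_succ <- all_succ[ord]
  best <- all_npc[all_succ == max(all_succ, na.rm = TRUE)][1]

  fit <- suppressWarnings(
    MASS::lda(scores[, seq_len(best), drop = FALSE], grouping = groups)
  )
  pred <- stats::predict(fit, scores[, seq_len(best), drop = FALSE])
  structure(list(
    n_pcs_retained = best,
    assignments = stats::setNames(as.character(pred$class),
      g$individuals$id),
    posterior = pred$posterior,
    scores = pred$x,
    xval_success = max(all_succ, na.rm = TRUE),
    success_by_npc = data.frame(n_pc = all_npc, success = all_succ)
  ), class = "dapc_result")
}

#' K-means clustering on PC scores with a BIC curve
#'
#' k-means (multiple seeded restarts, best inertia kept) on retained PC
#' scores for each k; BIC(k) = n ln(WSS/n) + k ln(n); the best k minimizes
#' BIC.
#'
#' @param g a \code{\link{genotype_matrix}}
#' @param k_range candidate cluster counts.
#' @param n_pc PCs retained for clustering.
#' @param n_start k-means restarts.
#' @param seed RNG seed.
#' @return list of class \code{kmeans_bic}: \code{bic_curve} (data.frame k,
#'   BIC), \code{best_k}, \code{assignments} (for best_k).
#' @export
kmeans_bic <- function(g, k_range = 1:11, n_pc = NULL, n_start = 15,
                       seed = 1) {
  n <- n_ind(g)
  k_range <- k_range[k_range >= 1 & k_range <= n - 1]
  if (is.null(n_pc)) n_pc <- min(n - 2, 50)
  scores <- pca_scores(g, n_pc)
  set.seed(seed)
  fits <- lapply(k_range, function(k) {
    if (k == 1) {
      wss <- sum(sweep(scores, 2, colMeans(scores), "-")^2)
      list(cluster = rep(1L, n), tot.withinss = wss)
    } else {
      tryCatch(
        stats::kmeans(scores, centers = k, nstart = n_start, iter.max = 50),
        error = function(e) stats::kmeans(scores, centers = k,
          nstart = n_start, iter.max = 50)
      )
    }
  })
  bic <- vapply(seq_along(k_range), function(i) {
    n * log(fits[[i]]$tot.withinss / n) + k_range[i] * log(n)
  }, numeric(1))
  best <- k_range[which.min(bic)]
  structure(list(
    bic_curve = data.frame(k = k_range, BIC = bic),
    best_k = best,
    assignments = stats::setNames(
      fits[[which(k_range == best)]]$cluster, g$individuals$id
    )
  ), class = "kmeans_bic")
}
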