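#' Broadcast a per-site table to individuals
#'
#' Environmental summaries are measured once per site (one buoy per
#' locality); individuals inherit their site's values.
#'
#' @param tab data.frame with a \code{site} column and numeric columns.
#' @param sites site label per individual (e.g. \code{\link{sites_of}}).
#' @param vars columns to use; default all numeric columns.
#' @return numeric matrix, one row per individual.
#' @export
broadcast_to_ind <- function(tab, sites, vars = NULL) {
  if (is.null(vars))
    vars <- setdiff(names(tab)[vapply(tab, is.numeric, logical(1))], "site")
  idx <- match(sites, tab$site)
  if (anyNA(idx)) stop("sites missing from table: ",
    paste(unique(sites[is.na(idx)]), collapse = ", "))
  m <- as.matrix(tab[idx, vars, drop = FALSE])
  rownames(m) <- NULL
  m
}

#' Iterative variance-inflation-factor screen
#'
#' Repeatedly drops the variable with the largest VIF (ties broken by
#' column order) until all VIFs are below \code{max_vif}.
#' VIF_j = 1/(1 - R2_j) from regressing variable j on the others.
#'
#' @param env data.frame with a \code{site} column and numeric predictor
#'   columns (or a plain numeric data.frame/matrix).
#' @param max_vif retain variables with VIF strictly below this.
#' @return \code{env} with only the retained predictor columns;
#'   \code{attr(,"dropped")} lists removals in order,
#'   \code{attr(,"vif")} the final VIFs.
#' @export
vif_screen <- function(env, max_vif = 10) {
  has_site <- is.data.frame(env) && "site" %in% names(env)
  vars <- if (has_site)
    setdiff(names(env)[vapply(env, is.numeric, logical(1))], "site")
  else colnames(as.data.frame(env))
  X <- as.matrix(as.data.frame(env)[, vars, drop = FALSE])
  if (length(vars) < 2) stop("vif_screen needs >= 2 variables")
  if (nrow(X) < length(vars) + 2)
    stop("vif_screen needs >= variables + 2 rows")
  vifs <- function(M) {
    vapply(seq_len(ncol(M)), function(j) {
      r2 <- suppressWarnings(
        summary(stats::lm(M[, j] ~ M[, -j, drop = FALSE]))$r.squared
      )
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  dropped <- character(0)
  while (ncol(X) >= 2) {
    v <- vifs(X)
    if (all(v < max_vif)) break
    worst <- which.max(v)   # ties -> first (column order)
    dropped <- c(dropped, colnames(X)[worst])
    X <- X[, -worst, drop = FALSE]
  }
  keep <- colnames(X)
  out <- if (has_site) env[, c("site", keep)] else
    as.data.frame(env)[, keep, drop = FALSE]
  attr(out, "dropped") <- dropped
  attr(out, "vif") <- if (ncol(X) >= 2) stats::setNames(vifs(X), keep) else
    stats::setNames(1, keep)
  out
}

# centered genotype response with the most common genotype imputed
rda_response <- function(g, scale = FALSE) {
  X <- g$dosages
  if (anyNA(X)) {
    for (l in which(colSums(is.na(X)) > 0)) {
      tab <- tabulate(X[, l] + 1L, nbins = 3)
      X[is.na(X[, l]), l] <- which.max(tab) - 1L
    }
  }
  X <- scale(X, center = TRUE, scale = scale)
  X[, !is.finite(colSums(X))] <- 0
  X
}

#' Redundancy analysis of a genotype matrix on predictors
#'
#' Multivariate least squares of the centered (mode-imputed) dosage matrix
#' on the predictors, followed by a PCA of the fitted values: the
#' constrained axes. With a \code{condition} matrix, genotypes and
#' predictors are first residualized on it (partial RDA). R-squared is
#' SS(fitted)/SS(total) with SS(total) taken before conditioning so that
#' variance fractions from full and partial fits are additive; the adjusted
#' R-squared applies the Ezekiel correction
#' \eqn{1 - (1 - R^2)(n-1)/(n-1-m)}. The overall permutation test permutes
#' rows of the (residualized) response and recomputes the pseudo-F; the
#' per-axis test uses the permutation distribution of each axis eigenvalue.
#'
#' @param g a \code{\link{genotype_matrix}} (or a plain numeric response
#'   matrix with individuals in rows).
#' @param predictors numeric matrix, one row per individual (site-level
#'   predictors broadcast via \code{\link{broadcast_to_ind}}).
#' @param condition optional numeric matrix to partial out.
#' @param n_perm permutations for the ANOVA-like tests (0 = skip).
#' @param blocks optional factor (one level per site) marking rows that
#'   share site-level predictor values. When given, permutations shuffle
#'   the site-to-predictor assignment instead of individual rows: with
#'   predictors measured once per site, sites are the exchangeable units,
#'   and free individual permutation is badly anti-conservative.
#' @param seed RNG seed for the permutations.
#' @param scale_genotypes scale dosage columns to unit variance (default
#'   FALSE: centered only).
#' @param axis_p also compute per-axis permutation p-values.
#' @return list of class \code{rda_fit}: \code{eig} (axis eigenvalues),
#'   \code{axes} (individual scores), \code{snp_loadings}, \code{R2},
#'   \code{R2_adj}, \code{anova} (model F and p; per-axis p when
#'   requested), \code{rank}, plus the matrices needed downstream.
#' @export
rda_fit <- function(g, predictors, condition = NULL, n_perm = 999,
                    blocks = NULL, seed = 1, scale_genotypes = FALSE,
                    axis_p = FALSE) {
  Y <- if (inherits(g, "genotype_matrix")) rda_response(g, scale_genotypes)
    else scale(as.matrix(g), center = TRUE, scale = scale_genotypes)
  n <- nrow(Y)
  X <- scale(as.matrix(predictors), center = TRUE, scale = FALSE)
  if (nrow(X) != n) stop("predictors not row-matched to individuals")
  x_scale <- sqrt(colSums(X^2))
  ss_tot <- sum(Y^2)
  m_cond <- 0L
  C <- NULL
  if (!is.null(condition)) {
    C <- scale(as.matrix(condition), center = TRUE, scale = FALSE)
    qc <- qr(C)
    m_cond <- qc$rank
    Y <- Y - qr.fitted(qc, Y)
    X <- X - qr.fitted(qc, X)
    # columns absorbed by the condition are numerically zero, not rank
    drop_cols <- sqrt(colSums(X^2)) < pmax(1e-8 * x_scale, 1e-12)
    X[, drop_cols] <- 0
  }
  qx <- qr(X)
  m <- qx$rank
  if (m >= n - 1) stop("rda_fit: more predictors than residual df")
  if (m == 0L) {
    return(structure(list(
      eig = numeric(0), axes = matrix(0, n, 0),
      snp_loadings = matrix(0, ncol(Y), 0),
      R2 = 0, R2_adj = 0,
      anova = list(F = NA_real_, p = NA_real_, axis_p = NULL),
      rank = 0L, n = n, df_res = n - 1 - m_cond,
      ss_fit = 0, ss_res = sum(Y^2), ss_tot = ss_tot,
      predictors = predictors, response_centered = Y
    ), class = "rda_fit"))
  }
  Qx <- qr.Q(qx)[, seq_len(m), drop = FALSE]
  W <- crossprod(Qx, Y)                    # m x L
  ss_fit <- sum(W^2)
  ss_res <- sum(Y^2) - ss_fit
  df_res <- n - 1 - m - m_cond
  sv <- svd(W)
  eig <- sv$d^2 / (n - 1)
  axes <- Qx %*% sv$u %*% diag(sv$d, length(sv$d))
  rownames(axes) <- rownames(Y)
  loadings <- sv$v
  if (inherits(g, "genotype_matrix"))
    rownames(loadings) <- g$loci$id
  R2 <- ss_fit / ss_tot
  R2_adj <- 1 - (1 - R2) * (n - 1) / (n - 1 - (m + m_cond))
  F_obs <- (ss_fit / m) / (ss_res / df_res)

  anova_tab <- list(F = F_obs, p = NA_real_, axis_p = NULL)
  if (n_perm > 0) {
    set.seed(seed)
    k_ax <- if (axis_p) length(sv$d) else 0
    perm_F <- numeric(n_perm)
    perm_eig <- if (k_ax) matrix(0, n_perm, k_ax) else NULL
    blocks <- if (!is.null(blocks)) factor(blocks)
    X0 <- scale(as.matrix(predictors), center = TRUE, scale = FALSE)
    for (b in seq_len(n_perm)) {
      if (is.null(blocks)) {
        # free permutation: shuffling the rows of the (residualized)
        # predictor basis against Y equals permuting the response rows
        Qp <- Qx[sample.int(n), , drop = FALSE]
        mp <- m
      } else {
        # site-level exchangeability: reassign each block's predictor
        # values to a permuted block, then refit (condition unchanged)
        lv <- levels(blocks)
        remap <- lv[sample.int(length(lv))]
        rep_rows <- match(blocks, lv)
        Xp <- X0[match(remap[rep_rows], blocks), , drop = FALSE]
        if (!is.null(C)) {
          Xp <- Xp - qr.fitted(qr(C), Xp)
          Xp[, sqrt(colSums(Xp^2)) < pmax(1e-8 * x_scale, 1e-12)] <- 0
        }
        qp <- qr(Xp)
        mp <- qp$rank
        if (mp == 0L) {
          perm_F[b] <- 0
          next
        }
        Qp <- qr.Q(qp)[, seq_len(mp), drop = FALSE]
      }
      Wp <- crossprod(Qp, Y)
      sf <- sum(Wp^2)
      perm_F[b] <- (sf / mp) / ((sum(Y^2) - sf) / df_res)
      if (k_ax) {
        ep <- svd(Wp, nu = 0, nv = 0)$d^2 / (n - 1)
        perm_eig[b, ] <- ep[pmin(seq_len(k_ax), length(ep))] *
          (seq_len(k_ax) <= length(ep))
      }
    }
    anova_tab$p <- (1 + sum(perm_F >= F_obs)) / (n_perm + 1)
    if (k_ax)
      anova_tab$axis_p <- vapply(seq_len(k_ax), function(k) {
        (1 + sum(perm_eig[, k] >= eig[k])) / (n_perm + 1)
      }, numeric(1))
  }
  structure(list(
    eig = eig, axes = axes, snp_loadings = loadings,
    R2 = R2, R2_adj = R2_adj, anova = anova_tab,
    rank = m, n = n, df_res = df_res,
    ss_fit = ss_fit, ss_res = ss_res, ss_tot = ss_tot,
    predictors = predictors, response_centered = Y
  ), class = "rda_fit")
}

#' @export
print.rda_fit <- function(x, ...) {
  cat(sprintf(
    "rda_fit: %d individuals, rank %d; R2 = %.4f (adj %.4f), F = %.3f, p = %s\n",
    x$n, x$rank, x$R2, x$R2_adj, x$anova$F,
    format(x$anova$p)
  ))
  invisible(x)
}

#' Ezekiel adjusted R-squared
#' @param R2 unadjusted proportion of variance explained.
#' @param n observations.
#' @param m predictors.
#' @return adjusted R-squared.
#' @export
adj_r2 <- function(R2, n, m) 1 - (1 - R2) * (n - 1) / (n - 1 - m)

#' Genotype-environment outliers from RDA axis z-scores
#'
#' Each SNP is summarized by its z-score vector on the retained constrained
#' axes: the regression coefficient of the SNP on each axis divided by the
#' SNP's residual standard deviation (the standardization used by
#' PCA-scan methodology; it makes loci comparable regardless of their
#' variance). Outliers are flagged by robust Mahalanobis distance (MCD
#' location/scatter), rescaled by the genomic inflation factor and referred
#' to a chi-square on n_axes df; q-values by Benjamini-Hochberg. Flagged
#' SNPs are assigned to the environmental predictor with the largest
#' absolute correlation with their (imputed) dosages.
#'
#' @param fit an \code{\link{rda_fit}}.
#' @param n_axes number of retained axes (two by default: the axes that
#'   carry an environmental signal in practice).
#' @param fdr_q flag SNPs with q below this.
#' @param seed seed for the MCD subsampling.
#' @return data.frame of class \code{gea_outliers}: per SNP \code{D2},
#'   \code{p}, \code{q}, \code{flagged}, \code{assigned_var},
#'   \code{r_assigned}; \code{attr(,"lambda")}.
#' @export
gea_outliers <- function(fit, n_axes = 2, fdr_q = 0.1, seed = 1) {
  if (n_axes > length(fit$eig)) stop("n_axes exceeds available axes")
  # axis coefficients b_lk = d_k v_lk, standardized by the per-SNP
  # residual sd after the constrained fit
  d_sv <- sqrt(fit$eig * (fit$n - 1))
  B <- sweep(fit$snp_loadings, 2, d_sv, "*")
  res_ss <- pmax(colSums(fit$response_centered^2) - rowSums(B^2), 1e-12)
  res_sd <- sqrt(res_ss / (fit$n - fit$rank - 1))
  Z <- sweep(B[, seq_len(n_axes), drop = FALSE], 1, res_sd, "/")
  set.seed(seed)
  rob <- tryCatch(
    MASS::cov.rob(Z, method = "mcd"),
    error = function(e) list(center = colMeans(Z), cov = stats::cov(Z))
  )
  D2 <- stats::mahalanobis(Z, rob$center, rob$cov)
  lambda <- stats::median(D2) / stats::qchisq(0.5, n_axes)
  p <- stats::pchisq(D2 / lambda, n_axes, lower.tail = FALSE)
  q <- stats::p.adjust(p, "BH")
  flagged <- q < fdr_q
  assigned <- rep(NA_character_, length(p))
  r_assigned <- rep(NA_real_, length(p))
  if (any(flagged)) {
    pred <- as.matrix(fit$predictors)
    # correlations against uncentered predictors equal those against the
    # centered response used in the fit
    cors <- suppressWarnings(stats::cor(fit$response_centered[, flagged,
      drop = FALSE], pred))
    cors[is.na(cors)] <- 0
    pick <- apply(abs(cors), 1, which.max)
    assigned[flagged] <- colnames(pred)[pick]
    r_assigned[flagged] <- cors[cbind(seq_along(pick), pick)]
  }
  out <- data.frame(
    id = rownames(fit$snp_loadings), D2 = D2, p = p, q = q,
    flagged = flagged, assigned_var = assigned, r_assigned = r_assigned,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "lambda") <- lambda
  class(out) <- c("gea_outliers", "data.frame")
  out
}

#' Spatial eigenvector predictors (PCNM)
#'
#' Principal coordinates of the neighbour matrix: distances are truncated
#' at the longest minimum-spanning-tree edge (larger entries replaced by
#' four times the truncation), double-centered and eigen-decomposed;
#' eigenvectors with positive eigenvalues are returned in eigenvalue order
#' (PCNM1, PCNM2, ...).
#'
#' @param dist square water-distance matrix with site dimnames.
#' @return matrix sites x axes (columns PCNM1..), with eigenvalues in
#'   \code{attr(,"values")} and the truncation distance in
#'   \code{attr(,"threshold")}.
#' @export
pcnm_axes <- function(dist) {
  if (nrow(dist) < 3) stop("pcnm_axes needs >= 3 sites")
  d <- stats::as.dist(dist)
  fit <- vegan::pcnm(d)
  m <- fit$vectors
  colnames(m) <- paste0("PCNM", seq_len(ncol(m)))
  rownames(m) <- rownames(as.matrix(dist))
  attr(m, "values") <- fit$values[seq_len(ncol(m))]
  attr(m, "threshold") <- fit$threshold
  m
}

#' Environment-versus-geography variance partitioning
#'
#' Three redundancy analyses decompose the explainable genotypic variance:
#' the full model (environment plus space), environment conditioned on
#' space (unique environmental fraction a), and space conditioned on
#' environment (unique spatial fraction c); the joint fraction
#' b = full - a - c. Permutation p-values use free permutation for the full
#' model and residual permutation under the reduced model for the partial
#' fits; the joint fraction is not testable.
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param env_pred individual-level environmental predictor matrix
#'   (VIF-screened).
#' @param space_pred individual-level spatial predictor matrix (PCNM axes
#'   broadcast to individuals).
#' @param n_perm permutations.
#' @param blocks optional site factor passed to \code{\link{rda_fit}}
#'   (site-level predictors make sites the exchangeable units).
#' @param seed RNG seed.
#' @return data.frame of class \code{var_partition}: one row per fraction
#'   (full, env_unique, space_unique, joint) with R2, R2_adj, F, p.
#' @export
variance_partition <- function(g, env_pred, space_pred, n_perm = 999,
                               blocks = NULL, seed = 1) {
  full <- rda_fit(g, cbind(env_pred, space_pred), n_perm = n_perm,
    blocks = blocks, seed = seed)
  env_u <- rda_fit(g, env_pred, condition = space_pred, n_perm = n_perm,
    blocks = blocks, seed = seed)
  spa_u <- rda_fit(g, space_pred, condition = env_pred, n_perm = n_perm,
    blocks = blocks, seed = seed)
  joint_r2 <- full$R2 - env_u$R2 - spa_u$R2
  n <- full$n
  out <- data.frame(
    fraction = c("full", "env_unique", "space_unique", "joint"),
    R2 = c(full$R2, env_u$R2, spa_u$R2, joint_r2),
    R2_adj = c(full$R2_adj, env_u$R2_adj, spa_u$R2_adj,
      full$R2_adj - env_u$R2_adj - spa_u$R2_adj),
    F = c(full$anova$F, env_u$anova$F, spa_u$anova$F, NA_real_),
    p = c(full$anova$p, env_u$anova$p, spa_u$anova$p, NA_real_),
    stringsAsFactors = FALSE
  )
  class(out) <- c("var_partition", "data.frame")
  out
}

#' Marginal significance of each predictor in an RDA
#'
#' Each variable is tested by a partial RDA conditioned on all the others
#' (marginal permutation F-test).
#'
#' @param g a \code{\link{genotype_matrix}}.
#' @param predictors individual-level predictor matrix.
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @return data.frame: variable, variance (SS_fit/(n-1)), F, p.
#' @export
rda_terms <- function(g, predictors, n_perm = 999, blocks = NULL,
                      seed = 1) {
  predictors <- as.matrix(predictors)
  rows <- lapply(seq_len(ncol(predictors)), function(j) {
    fit <- rda_fit(g, predictors[, j, drop = FALSE],
      condition = predictors[, -j, drop = FALSE],
      n_perm = n_perm, blocks = blocks, seed = seed)
    data.frame(
      variable = colnames(predictors)[j],
      variance = fit$ss_fit / (fit$n - 1),
      F = fit$anova$F, p = fit$anova$p, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
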