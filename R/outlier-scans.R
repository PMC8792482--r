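# Weir & Cockerham variance components for one locus across r populations.
# n: per-pop called sample sizes, p: per-pop alt frequencies, h: per-pop
# observed het proportions. Returns c(a, b, c) (among-pop, among-individual,
# within-individual). corrected=FALSE drops the finite-sample terms, the
# null form whose ratio is chi-square distributed under neutrality.
wc_components <- function(n, p, h, corrected = TRUE) {
  r <- length(n)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  if (corrected) {
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  } else {
    a <- (nbar / nc) * s2
    b <- pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4
  }
  c(a = a, b = b, c = hbar / 2)
}

# per-locus components across all sites; returns matrix loci x (a,b,c)
# plus per-locus expected heterozygosity of the pooled frequencies.
wc_locus_table <- function(g, corrected = TRUE) {
  site_list <- unique(sites_of(g))
  r <- length(site_list)
  if (r < 2) stop("need >= 2 sites")
  L <- n_loci(g)
  n <- p <- h <- matrix(0, r, L)
  for (k in seq_len(r)) {
    d <- site_dosages(g, site_list[k])
    n[k, ] <- colSums(!is.na(d))
    p[k, ] <- colMeans(d, na.rm = TRUE) / 2
    h[k, ] <- colMeans(d == 1L, na.rm = TRUE)
  }
  comp <- matrix(NA_real_, L, 3, dimnames = list(NULL, c("a", "b", "c")))
  for (l in seq_len(L)) {
    ok <- n[, l] >= 2
    if (sum(ok) < 2) next
    comp[l, ] <- wc_components(n[ok, l], p[ok, l], h[ok, l], corrected)
  }
  ptot <- colSums(n * p) / colSums(n)
  list(comp = comp, he = 2 * ptot * (1 - ptot))
}

#' PCA-based outlier scan (Mahalanobis on component loadings)
#'
#' Dosages are centered and scaled by \eqn{\sqrt{2p(1-p)}} (missing values
#' mean-imputed), individuals projected onto K principal components, and
#' each SNP summarized by the vector of multiple-regression coefficients of
#' its scaled dosages on the K component scores. Outliers are flagged by
#' robust Mahalanobis distance of these vectors, rescaled by the genomic
#' inflation factor \eqn{\lambda = median(D^2)/median(\chi^2_K)}; p-values
#' are upper-tail chi-square on K df, q-values Benjamini-Hochberg.
#'
#' @param g a \code{\link{genotype_matrix}}
#' @param K number of principal components; default picks the Cattell
#'   elbow of the eigenvalue scree (largest drop), capped at 20.
#' @param maf minor-allele-frequency screen before the scan.
#' @param seed seed for the robust covariance (MCD) subsampling.
#' @return data.frame: chrom, pos, id, keep (passed the MAF screen), stat
#'   (lambda-scaled D2), p, q; \code{attr(,"lambda")}, \code{attr(,"K")}.
#' @export
pca_scan <- function(g, K = NULL, maf = 0.05, seed = 1) {
  p <- allele_freqs(g)$freq
  keep <- !is.na(p) & pmin(p, 1 - p) >= maf
  d <- g$dosages[, keep, drop = FALSE]
  pk <- colMeans(d, na.rm = TRUE) / 2
  X <- sweep(d, 2, 2 * pk, "-")
  X[is.na(X)] <- 0
  X <- sweep(X, 2, sqrt(2 * pk * (1 - pk)), "/")
  n <- nrow(X)
  sv <- svd(X, nu = min(n - 1, 30), nv = 0)
  if (is.null(K)) {
    ev <- sv$d[seq_len(min(20, length(sv$d) - 1))]^2
    K <- which.max(ev[-length(ev)] - ev[-1])
  }
  if (K >= n) stop("pca_scan: K must be < number of individuals")
  U <- sv$u[, seq_len(K), drop = FALSE]    # orthonormal scores
  Z <- crossprod(U, X)                     # K x L regression coefficients
  # standardize to t-like scores using residual variance per SNP
  res <- colSums(X^2) - colSums(Z^2)
  sigma <- sqrt(pmax(res, 1e-12) / (n - K - 1))
  Z <- sweep(Z, 2, sigma, "/")
  set.seed(seed)
  rob <- tryCatch(
    MASS::cov.rob(t(Z), method = "mcd"),
    error = function(e) list(center = rowMeans(Z), cov = stats::cov(t(Z)))
  )
  D2 <- stats::mahalanobis(t(Z), rob$center, rob$cov)
  lambda <- stats::median(D2) / stats::qchisq(0.5, K)
  pval <- stats::pchisq(D2 / lambda, K, lower.tail = FALSE)
  out <- g$loci[, c("chrom", "pos", "id")]
  out$keep <- keep
  out$stat <- out$p <- out$q <- NA_real_
  out$stat[keep] <- D2 / lambda
  out$p[keep] <- pval
  out$q[keep] <- stats::p.adjust(pval, "BH")
  attr(out, "lambda") <- lambda
  attr(out, "K") <- K
  out
}

#' FST outlier scan against a trimmed chi-square null
#'
#' Per-locus multi-population Weir-Cockerham FST without finite-sample
#' correction; the neutral null \eqn{F df / \bar F \sim \chi^2_{df}} is fit
#' by maximum likelihood on the distribution with its lowest and highest
#' \code{trim} fractions removed (truncated-likelihood fit, so the trimming
#' itself does not bias the null). Right-tail p-values from the fitted
#' null; q-values Benjamini-Hochberg.
#'
#' @param g a \code{\link{genotype_matrix}} with >= 2 sites.
#' @param trim fraction trimmed from each tail when fitting the null.
#' @param Hmin loci with pooled expected heterozygosity below this are
#'   excluded (low-He loci have unstable single-locus FST).
#' @return data.frame: chrom, pos, id, keep, fst (uncorrected), p, q;
#'   \code{attr(,"fstbar")}, \code{attr(,"df")} of the fitted null.
#' @export
fst_scan <- function(g, trim = 0.05, Hmin = 0.1) {
  wt <- wc_locus_table(g, corrected = FALSE)
  fst <- wt$comp[, "a"] / rowSums(wt$comp)
  keep <- !is.na(fst) & wt$he >= Hmin & rowSums(wt$comp) > 0
  x <- fst[keep]
  if (length(x) < 50) stop("fst_scan: fewer than 50 usable loci")
  qs <- stats::quantile(x, c(trim, 1 - trim), names = FALSE)
  xt <- x[x >= qs[1] & x <= qs[2]]
  if (length(xt) < 50) stop("fst_scan: fewer than 50 loci after trim")
  # truncated chi-square ML for (mean fstbar, df)
  nll <- function(par) {
    m <- exp(par[1]); df <- exp(par[2])
    z <- xt * df / m
    lo <- qs[1] * df / m; hi <- qs[2] * df / m
    pm <- stats::pchisq(hi, df) - stats::pchisq(lo, df)
    if (!is.finite(pm) || pm <= 0) return(1e10)
    -sum(stats::dchisq(z, df, log = TRUE) + log(df / m)) +
      length(z) * log(pm)
  }
  fit <- stats::optim(c(log(mean(xt)), log(max(2, length(unique(sites_of(g))) - 1))),
    nll, method = "Nelder-Mead")
  m <- exp(fit$par[1]); df <- exp(fit$par[2])
  pval <- stats::pchisq(x * df / m, df, lower.tail = FALSE)
  out <- g$loci[, c("chrom", "pos", "id")]
  out$keep <- keep
  out$fst <- fst
  out$p <- out$q <- NA_real_
  out$p[keep] <- pval
  out$q[keep] <- stats::p.adjust(pval, "BH")
  attr(out, "fstbar") <- m
  attr(out, "df") <- df
  out
}

#' Combine scan flags into the neutral/outlier/adaptive partition
#'
#' The outlier set is the union of every differentiation-method flag plus
#' the genotype-environment (RDA) flags; the putatively adaptive set is the
#' intersection of the differentiation-method flags (including an external
#' method's flags when supplied); the neutral set is the complement of the
#' outlier union.
#'
#' @param flags named list of logical vectors (one per differentiation
#'   method, e.g. pca_scan / fst_scan q < 0.1), all of length n_loci;
#'   NA entries (loci a method did not test) count as not flagged.
#' @param rda_flags logical vector of GEA (RDA) outlier flags, or NULL.
#' @param external optional logical flag vector from an externally run
#'   method (e.g. a Bayesian FST scan), included in both union and
#'   intersection.
#' @return list of class \code{snp_partition}: \code{neutral},
#'   \code{outlier_union}, \code{adaptive_intersection} (integer locus
#'   indices) and \code{class} (factor neutral/outlier/adaptive per locus).
#' @export
combine_partition <- function(flags, rda_flags = NULL, external = NULL) {
  flags <- lapply(flags, function(f) !is.na(f) & f)
  if (!is.null(external)) flags$external <- !is.na(external) & external
  L <- unique(vapply(flags, length, integer(1)))
  if (length(L) != 1) stop("combine_partition: flag length mismatch")
  if (!is.null(rda_flags)) {
    if (length(rda_flags) != L) stop("combine_partition: flag length mismatch")
    rda_flags <- !is.na(rda_flags) & rda_flags
  } else {
    rda_flags <- rep(FALSE, L)
  }
  union_flag <- Reduce(`|`, flags) | rda_flags
  inter_flag <- Reduce(`&`, flags)
  cls <- factor(
    ifelse(inter_flag, "adaptive", ifelse(union_flag, "outlier", "neutral")),
    levels = c("neutral", "outlier", "adaptive")
  )
  structure(list(
    neutral = which(!union_flag),
    outlier_union = which(union_flag),
    adaptive_intersection = which(inter_flag),
    class = cls
  ), class = "snp_partition")
}

#' @export
print.snp_partition <- function(x, ...) {
  cat("snp_partition:", length(x$class), "SNPs ->",
    length(x$neutral), "neutral,",
    length(x$outlier_union), "outliers (union),",
    length(x$adaptive_intersection), "adaptive (intersection)\n")
  invisible(x)
}
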