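site_dosages <- function(g, site) {
  keep <- sites_of(g) == site
  if (!any(keep)) stop("site not present: ", site)
  g$dosages[keep, , drop = FALSE]
}

#' Observed heterozygosity of a site
#'
#' Mean over loci of the proportion of heterozygous calls among called
#' genotypes; loci with zero calls in the site are excluded.
#'
#' @param g a \code{\link{genotype_matrix}}
#' @param site site label.
#' @return Ho, a proportion.
#' @export
het_obs <- function(g, site) {
  d <- site_dosages(g, site)
  n_called <- colSums(!is.na(d))
  n_het <- colSums(d == 1L, na.rm = TRUE)
  mean((n_het / n_called)[n_called > 0])
}

# per-locus unbiased gene diversity within one site:
# h = (2n/(2n-1)) (1 - p^2 - q^2), n = called individuals; n < 2 -> NA
gene_diversity <- function(d) {
  n <- colSums(!is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  h <- (2 * n / (2 * n - 1)) * (1 - p^2 - (1 - p)^2)
  h[n < 2] <- NA_real_
  h
}

#' Expected heterozygosity (unbiased gene diversity) of a site
#'
#' Per-locus \eqn{\hat h = \frac{2n}{2n-1}(1 - p^2 - q^2)} with n the called
#' individuals (the small-sample correction used by hierfstat-style basic
#' stats); He is the mean over loci. Loci with n < 2 are excluded.
#'
#' @inheritParams het_obs
#' @return He, a proportion.
#' @export
het_exp <- function(g, site) {
  mean(gene_diversity(site_dosages(g, site)), na.rm = TRUE)
}

#' Rarefied allelic richness per site
#'
#' Expected number of distinct alleles in a subsample of \code{rarefy_to}
#' genes: per locus \eqn{A_r = \sum_i [1 - C(2n - N_i, g^*)/C(2n, g^*)]}
#' with \eqn{N_i} the count of allele i; the site value is the mean over
#' loci. The default rarefaction target is the smallest per-site gene count
#' over sites and loci, making values comparable across sites.
#'
#' @param g a \code{\link{genotype_matrix}}
#' @param rarefy_to gene count g* (>= 2); default the minimum 2n over
#'   sites and loci with at least one call.
#' @return named numeric vector of per-site allelic richness.
#' @export
allelic_richness <- function(g, rarefy_to = NULL) {
  site_list <- unique(sites_of(g))
  counts <- lapply(site_list, function(s) {
    d <- site_dosages(g, s)
    n <- colSums(!is.na(d))
    alt <- colSums(d, na.rm = TRUE)
    cbind(n2 = 2 * n, alt = alt)
  })
  if (is.null(rarefy_to)) {
    mins <- vapply(counts, function(x) {
      v <- x[, "n2"]
      if (all(v == 0)) Inf else min(v[v > 0])
    }, numeric(1))
    rarefy_to <- min(mins)
  }
  if (rarefy_to < 2) stop("rarefy_to must be >= 2")
  ar <- vapply(counts, function(x) {
    n2 <- x[, "n2"]; alt <- x[, "alt"]; ref <- n2 - alt
    ok <- n2 >= rarefy_to
    miss_alt <- exp(lchoose(n2 - alt, rarefy_to) - lchoose(n2, rarefy_to))
    miss_ref <- exp(lchoose(n2 - ref, rarefy_to) - lchoose(n2, rarefy_to))
    mean((2 - miss_alt - miss_ref)[ok])
  }, numeric(1))
  names(ar) <- site_list
  ar
}

#' Site-level FIS with a bootstrap confidence interval
#'
#' FIS = 1 - Ho/Hs with Ho and Hs the multilocus means of observed
#' heterozygosity and unbiased gene diversity. The CI resamples loci with
#' replacement (the convention of the bootstrap routine this mirrors);
#' 2.5/97.5 percentiles of the resampled FIS.
#'
#' @inheritParams het_obs
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed for the resampling.
#' @return list with \code{fis}, \code{lo}, \code{hi}.
#' @export
fis <- function(g, site, n_boot = 1000, seed = 1) {
  d <- site_dosages(g, site)
  n_called <- colSums(!is.na(d))
  ho <- colSums(d == 1L, na.rm = TRUE) / n_called
  hs <- gene_diversity(d)
  ok <- n_called > 0 & !is.na(hs)
  ho <- ho[ok]; hs <- hs[ok]
  poly <- hs > 0
  if (sum(poly) < 2) stop("fis: fewer than 2 polymorphic loci")
  if (mean(hs) == 0) return(list(fis = NA_real_, lo = NA_real_, hi = NA_real_))
  point <- 1 - mean(ho) / mean(hs)
  set.seed(seed)
  L <- length(ho)
  reps <- vapply(seq_len(n_boot), function(i) {
    k <- sample.int(L, L, replace = TRUE)
    1 - mean(ho[k]) / mean(hs[k])
  }, numeric(1))
  ci <- stats::quantile(reps, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
  list(fis = point, lo = ci[1], hi = ci[2])
}

#' Ritland pairwise relatedness within a site
#'
#' Moment estimator weighting allele sharing by reference allele
#' frequencies; for a biallelic locus with frequencies p, q:
#' \eqn{r_l(x,y) = 2 (S_{xA}S_{yA}/p + S_{xa}S_{ya}/q - 1)} with S the allele
#' proportion (0, 0.5, 1) in each genotype, and the multilocus estimate the
#' (weight-1) mean over loci. Expectation 0 for unrelated pairs and 0.5 for
#' parent-offspring pairs. Single-locus values are unbounded.
#'
#' @inheritParams het_obs
#' @param freqs optional reference allele (alt) frequencies to use instead
#'   of the site-internal sample frequencies (the default scope, matching a
#'   per-site analysis).
#' @param min_loci pairs with fewer jointly called polymorphic loci are
#'   reported NA.
#' @return list with \code{r} (symmetric pairwise matrix, NA diagonal) and
#'   \code{mean} (mean over unordered pairs).
#' @export
ritland_relatedness <- function(g, site, freqs = NULL, min_loci = 10) {
  d <- site_dosages(g, site)
  p <- if (is.null(freqs)) colMeans(d, na.rm = TRUE) / 2 else freqs
  keep <- !is.na(p) & p > 0 & p < 1
  d <- d[, keep, drop = FALSE]
  p <- p[keep]
  if (ncol(d) == 0L) stop("ritland_relatedness: no polymorphic loci")
  S <- d / 2                      # alt-allele proportion per genotype
  M <- !is.na(S)
  S0 <- S; S0[!M] <- 0
  Sc0 <- 1 - S; Sc0[!M] <- 0
  # per-pair sum over jointly called loci of (SxSy/p + Sx'Sy'/q - 1)
  A <- tcrossprod(sweep(S0, 2, p, "/"), S0)
  B <- tcrossprod(sweep(Sc0, 2, 1 - p, "/"), Sc0)
  njoint <- tcrossprod(M * 1)
  r <- 2 * (A + B - njoint) / njoint
  r[njoint < min_loci] <- NA_real_
  diag(r) <- NA_real_
  dimnames(r) <- list(rownames(d), rownames(d))
  list(r = r, mean = mean(r[upper.tri(r)], na.rm = TRUE))
}

#' Standardized multilocus heterozygosity
#'
#' Per individual: the proportion of its typed loci that are heterozygous,
#' divided by the mean observed heterozygosity of those same loci across all
#' individuals. With no missing data the population mean is exactly 1.
#'
#' @param g a \code{\link{genotype_matrix}}
#' @return named numeric vector, one value per individual (NA when an
#'   individual has zero typed loci).
#' @export
smlh <- function(g) {
  if (n_ind(g) < 2) stop("smlh needs >= 2 individuals")
  d <- g$dosages
  locus_het <- colMeans(d == 1L, na.rm = TRUE)   # per-locus het rate
  typed <- !is.na(d)
  num <- rowSums(d == 1L, na.rm = TRUE) / rowSums(typed)
  den <- (typed %*% ifelse(is.na(locus_het), 0, locus_het)) / rowSums(typed)
  out <- as.numeric(num / den)
  out[rowSums(typed) == 0] <- NA_real_
  names(out) <- g$individuals$id
  out
}

#' Per-site diversity summary table
#'
#' One row per site: Ho, He, FIS with CI, rarefied allelic richness, mean
#' Ritland relatedness, and the number of genotyped individuals.
#'
#' @param g a \code{\link{genotype_matrix}}
#' @param n_boot,seed passed to \code{\link{fis}}.
#' @param rarefy_to passed to \code{\link{allelic_richness}}.
#' @return data.frame with columns site, n, Ho, He, FIS, FIS_lo, FIS_hi,
#'   Ar, relatedness.
#' @export
diversity_summary <- function(g, n_boot = 1000, seed = 1, rarefy_to = NULL) {
  site_list <- unique(sites_of(g))
  ar <- allelic_richness(g, rarefy_to)
  rows <- lapply(site_list, function(s) {
    fi <- fis(g, s, n_boot = n_boot, seed = seed)
    data.frame(
      site = s, n = sum(sites_of(g) == s),
      Ho = het_obs(g, s), He = het_exp(g, s),
      FIS = fi$fis, FIS_lo = fi$lo, FIS_hi = fi$hi,
      Ar = unname(ar[s]),
      relatedness = ritland_relatedness(g, s)$mean,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
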