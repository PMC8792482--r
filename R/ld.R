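# Pairwise squared correlation of dosage vectors with missing-data support.
# Returns list(r2 = LxL matrix, njoint = LxL joint-call counts).
dosage_r2_matrix <- function(d) {
  L <- ncol(d)
  if (!anyNA(d)) {
    r <- suppressWarnings(stats::cor(d))
    list(r2 = r^2, njoint = matrix(nrow(d), L, L))
  } else {
    M <- (!is.na(d)) * 1
    X <- d
    X[is.na(d)] <- 0
    n <- crossprod(M)
    sx <- crossprod(X, M)
    sxx <- crossprod(X^2, M)
    sxy <- crossprod(X)
    num <- n * sxy - sx * t(sx)
    den2 <- (n * sxx - sx^2) * t(n * sxx - sx^2)
    r2 <- ifelse(den2 > 0 & n >= 2, num^2 / den2, NA_real_)
    list(r2 = r2, njoint = n)
  }
}

#' Pairwise linkage disequilibrium (r-squared) within a site
#'
#' r-squared is the squared Pearson correlation of dosage vectors over
#' jointly called individuals (the composite/Burrows-equivalent measure for
#' unphased data). Pairs are labelled intra- or interchromosomal; bp
#' distance is reported for intrachromosomal pairs. When the number of
#' interchromosomal pairs exceeds \code{max_pairs} a seeded uniform
#' subsample is taken (intrachromosomal pairs are always kept).
#'
#' @param g a \code{\link{genotype_matrix}}
#' @param site site label, or NULL for all individuals.
#' @param max_pairs cap on interchromosomal pairs retained.
#' @param seed seed for the interchromosomal subsample.
#' @param min_joint pairs with fewer jointly called individuals are skipped
#'   (counted in \code{attr(,"n_skipped")}).
#' @return data.frame of class \code{ld_result}: columns \code{i, j}
#'   (locus indices), \code{chrom} (intra pairs, else NA), \code{r2},
#'   \code{dist_bp} (intra pairs, else NA), \code{intra}, \code{S} (joint
#'   sample size).
#' @export
pairwise_r2 <- function(g, site = NULL, max_pairs = 2e6, seed = 1,
                        min_joint = 10) {
  d <- if (is.null(site)) g$dosages else site_dosages(g, site)
  L <- ncol(d)
  if (L < 2) stop("pairwise_r2 needs >= 2 loci")
  ps <- dosage_r2_matrix(d)
  idx <- which(upper.tri(ps$r2))
  i <- (idx - 1L) %% L + 1L
  j <- (idx - 1L) %/% L + 1L
  chrom_i <- g$loci$chrom[i]
  intra <- chrom_i == g$loci$chrom[j]
  out <- data.frame(
    i = i, j = j,
    chrom = ifelse(intra, chrom_i, NA_character_),
    r2 = ps$r2[idx],
    dist_bp = ifelse(intra, abs(g$loci$pos[i] - g$loci$pos[j]), NA_real_),
    intra = intra,
    S = ps$njoint[idx],
    stringsAsFactors = FALSE
  )
  usable <- !is.na(out$r2) & out$S >= min_joint
  n_skipped <- sum(!usable)
  out <- out[usable, , drop = FALSE]
  n_inter <- sum(!out$intra)
  if (n_inter > max_pairs) {
    set.seed(seed)
    keep_inter <- sample(which(!out$intra), max_pairs)
    out <- out[sort(c(which(out$intra), keep_inter)), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("ld_result", "data.frame")
  out
}

#' Critical r-squared from unlinked (interchromosomal) pairs
#'
#' Root-transforms the interchromosomal r-squared values, takes the 95th
#' percentile, and squares back: LD above this level is attributed to
#' physical linkage.
#'
#' @param ld an \code{\link{pairwise_r2}} result.
#' @param probs percentile of the root-transformed distribution.
#' @return critical r-squared (scalar).
#' @export
critical_r2 <- function(ld, probs = 0.95) {
  x <- ld$r2[!ld$intra]
  if (length(x) < 100) stop("critical_r2 needs >= 100 interchromosomal pairs")
  stats::quantile(sqrt(x), probs, names = FALSE)^2
}

#' LOESS curve of LD decay with distance on one chromosome
#'
#' Degree-2 locally weighted regression (tricube weights) of r-squared on bp
#' distance for intrachromosomal pairs, evaluated on a 200-point grid from 0
#' to the 99th percentile of pair distances.
#'
#' @param ld an \code{\link{pairwise_r2}} result.
#' @param chrom chromosome label.
#' @param span LOESS span.
#' @param min_pairs minimum intrachromosomal pairs required.
#' @return list of class \code{loess_curve} with \code{dist}, \code{r2},
#'   \code{chrom}, \code{span}; or NULL if too few pairs.
#' @export
loess_decay <- function(ld, chrom, span = 0.5, min_pairs = 50) {
  k <- ld$intra & !is.na(ld$chrom) & ld$chrom == chrom
  if (sum(k) < min_pairs) return(NULL)
  dat <- data.frame(d = ld$dist_bp[k], r2 = ld$r2[k])
  fit <- stats::loess(r2 ~ d, data = dat, span = span, degree = 2,
    family = "gaussian", control = stats::loess.control(surface = "direct"))
  grid <- seq(0, stats::quantile(dat$d, 0.99, names = FALSE), length.out = 200)
  structure(
    list(dist = grid, r2 = as.numeric(stats::predict(fit, data.frame(d = grid))),
      chrom = chrom, span = span),
    class = "loess_curve"
  )
}

#' Per-chromosome thinning distances from the LOESS/critical-r2 crossing
#'
#' For each chromosome the thinning distance is the smallest grid distance
#' at which the LOESS curve first falls to or below the critical r-squared.
#' A chromosome whose curve lies entirely below the critical value (or with
#' too few intrachromosomal pairs) is not thinned (distance NA); a curve
#' that never falls below it yields the largest grid distance.
#'
#' @param ld an \code{\link{pairwise_r2}} result.
#' @param crit critical r-squared (see \code{\link{critical_r2}}).
#' @param span LOESS span.
#' @return list of class \code{thinning_plan}: \code{critical_r2} and
#'   \code{per_chrom} (named numeric, NA = no thinning).
#' @export
thinning_plan <- function(ld, crit, span = 0.5) {
  chroms <- unique(ld$chrom[ld$intra & !is.na(ld$chrom)])
  chroms <- chroms[order(chroms)]
  per <- vapply(chroms, function(ch) {
    cv <- loess_decay(ld, ch, span = span)
    if (is.null(cv)) return(NA_real_)
    if (all(cv$r2 <= crit, na.rm = TRUE)) return(NA_real_)
    below <- which(cv$r2 <= crit)
    if (length(below) == 0) max(cv$dist) else cv$dist[min(below)]
  }, numeric(1))
  names(per) <- chroms
  structure(list(critical_r2 = crit, per_chrom = per),
    class = "thinning_plan")
}

#' @export
print.thinning_plan <- function(x, ...) {
  cat("thinning_plan: critical r2 =", signif(x$critical_r2, 4), "\n")
  for (ch in names(x$per_chrom)) {
    d <- x$per_chrom[[ch]]
    cat("  ", ch, ": ",
      if (is.na(d)) "no thinning" else paste0(round(d), " bp"), "\n", sep = "")
  }
  invisible(x)
}

#' Thin loci by a per-chromosome minimum distance
#'
#' Greedy left-to-right scan within each chromosome: a locus is kept iff its
#' position is at least the plan distance from the last kept locus.
#' Chromosomes without a plan distance are untouched.
#'
#' @param g a \code{\link{genotype_matrix}} (loci sorted by chrom, pos).
#' @param plan a \code{\link{thinning_plan}}, or a single distance applied
#'   to every chromosome.
#' @return a \code{\link{genotype_matrix}}.
#' @export
thin <- function(g, plan) {
  per <- if (inherits(plan, "thinning_plan")) plan$per_chrom else NULL
  keep <- logical(n_loci(g))
  for (ch in unique(g$loci$chrom)) {
    idx <- which(g$loci$chrom == ch)
    d <- if (is.null(per)) plan else {
      if (ch %in% names(per)) per[[ch]] else NA_real_
    }
    if (is.na(d) || d <= 0) {
      keep[idx] <- TRUE
      next
    }
    last <- -Inf
    for (k in idx) {
      if (g$loci$pos[k] - last >= d) {
        keep[k] <- TRUE
        last <- g$loci$pos[k]
      }
    }
  }
  subset_genotypes(g, loci = keep)
}
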