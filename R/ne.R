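ld_ne_transform <- function(r2_drift, S) {
  # LD -> Ne mapping of the single-sample method (random mating);
  # constants differ for small samples (S < 30).
  if (is.na(r2_drift)) return(NA_real_)
  if (r2_drift <= 0) return(Inf)
  if (S >= 30) {
    disc <- max(0, 1 / 9 - 2.76 * r2_drift)
    (1 / 3 + sqrt(disc)) / (2 * r2_drift)
  } else {
    disc <- max(0, 0.308^2 - 2.08 * r2_drift)
    (0.308 + sqrt(disc)) / (2 * r2_drift)
  }
}

ld_ne_bias <- function(S) {
  # expected sampling contribution to mean r2
  if (S >= 30) 1 / S + 3.19 / S^2 else 0.0018 + 0.907 / S + 4.44 / S^2
}

#' LD-based effective population size of a single sample
#'
#' Mean pairwise r-squared over locus pairs (after the Pcrit allele
#' frequency screen, applied on within-site frequencies) is corrected for
#' the sampling contribution expected at the harmonic-mean joint sample
#' size S, and transformed to an estimate of Ne. Confidence intervals come
#' from a delete-one-individual jackknife on the mean r-squared, carried
#' through the same transform via an effective-chi-square approximation.
#'
#' @param g a \code{\link{genotype_matrix}}
#' @param site site label, or NULL for all individuals.
#' @param pcrit loci with within-site minor allele frequency below this are
#'   dropped (rare alleles bias r-squared upward).
#' @param max_pairs cap on pairs used (seeded uniform subsample above it).
#' @param seed seed for the pair subsample.
#' @param min_joint minimum jointly called individuals per pair.
#' @param ci compute the jackknife interval (costs one extra pass per
#'   individual).
#' @return object of class \code{ne_estimate}: \code{ne}, \code{lo},
#'   \code{hi}, \code{r2} (mean), \code{r2_drift}, \code{S},
#'   \code{n_pairs}, \code{n_loci}, \code{pcrit}, \code{adjusted},
#'   \code{life_history}.
#' @export
ld_ne <- function(g, site = NULL, pcrit = 0.02, max_pairs = 2e6, seed = 1,
                  min_joint = 10, ci = TRUE) {
  d <- if (is.null(site)) g$dosages else site_dosages(g, site)
  n <- nrow(d)
  if (n < 2) stop("ld_ne needs >= 2 individuals")
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- !is.na(maf) & maf >= pcrit & maf > 0
  if (sum(keep) < 2) stop("ld_ne: < 2 loci after Pcrit screen")
  d <- d[, keep, drop = FALSE]
  L <- ncol(d)

  pair_mask <- function(ps) {
    m <- upper.tri(ps$r2) & !is.na(ps$r2) & ps$njoint >= min_joint
    m
  }
  ps <- dosage_r2_matrix(d)
  # Weir-style small-sample covariance scaling: the per-pair squared
  # correlation times (S/(S-1))^2, whose null expectation S^2/(S-1)^3
  # matches the 1/S + 3.19/S^2 sampling term the method subtracts.
  ps$r2 <- ps$r2 * (ps$njoint / (ps$njoint - 1))^2
  mask <- pair_mask(ps)
  idx <- which(mask)
  if (length(idx) > max_pairs) {
    set.seed(seed)
    idx <- sort(sample(idx, max_pairs))
    mask[] <- FALSE
    mask[idx] <- TRUE
  }
  if (length(idx) == 0) stop("ld_ne: no usable locus pairs")
  S <- 1 / mean(1 / ps$njoint[idx])          # harmonic mean joint n
  if (S < 30)
    message("ld_ne: harmonic mean sample size ", round(S, 1),
      " < 30; using the small-sample correction constants")
  r2_mean <- mean(ps$r2[idx])
  r2_drift <- r2_mean - ld_ne_bias(S)
  ne <- ld_ne_transform(r2_drift, S)

  lo <- hi <- NA_real_
  if (ci && n > 2) {
    jack <- vapply(seq_len(n), function(k) {
      psk <- dosage_r2_matrix(d[-k, , drop = FALSE])
      psk$r2 <- psk$r2 * (psk$njoint / (psk$njoint - 1))^2
      mk <- mask & !is.na(psk$r2) & psk$njoint >= 2
      mean(psk$r2[mk])
    }, numeric(1))
    jbar <- mean(jack)
    jvar <- (n - 1) / n * sum((jack - jbar)^2)
    if (jvar > 0) {
      # effective-df chi-square interval on the mean r2
      df_eff <- max(1, 2 * r2_mean^2 / jvar)
      r2_ci <- df_eff * r2_mean / stats::qchisq(c(0.975, 0.025), df_eff)
      ne_ci <- vapply(r2_ci - ld_ne_bias(S), ld_ne_transform, numeric(1),
        S = S)
      lo <- min(ne_ci)
      hi <- max(ne_ci)
    }
  }
  structure(list(
    ne = ne, lo = lo, hi = hi, r2 = r2_mean, r2_drift = r2_drift, S = S,
    n_pairs = length(idx), n_loci = L, pcrit = pcrit,
    adjusted = FALSE, life_history = NULL
  ), class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  lab <- if (isTRUE(x$adjusted)) "Nb-adjusted Ne" else "LD Ne"
  cat(sprintf(
    "%s = %s (CI %s - %s); mean r2 = %.5f, S = %.1f, %d pairs, Pcrit = %g\n",
    lab, format(round(x$ne, 1)), format(round(x$lo, 1)),
    format(round(x$hi, 1)), x$r2, x$S, x$n_pairs, x$pcrit
  ))
  invisible(x)
}

#' Life-history bias adjustment of a single-cohort Nb estimate
#'
#' A raw LD estimate from a single cohort estimates the number of breeders
#' Nb with bias from overlapping generations. The published two-trait
#' regression adjusts it, and a second regression converts adjusted Nb to
#' generational Ne:
#' \deqn{\hat N_b^{adj} = \hat N_b / (c_1 - c_2 \log_{10}(AL/\alpha))}
#' \deqn{\hat N_e = \hat N_b^{adj} / (d_1 + d_2 \log_{10}(AL/\alpha))}
#' Coefficients default to the published two-trait values (1.103, 0.245;
#' 0.485, 0.758) and can be overridden (e.g. with three-trait values that
#' also use CVf, taken from the cited reference's tables). CIs are
#' transformed by the same scalars.
#'
#' @param raw an \code{\link{ld_ne}} estimate from a single-cohort sample.
#' @param AL adult life span, years.
#' @param alpha age at maturity, years (AL > alpha >= 1).
#' @param CVf CV of age-specific fecundity (recorded; used only if
#'   three-trait coefficients are supplied).
#' @param coef_adj,coef_conv numeric length-2 coefficient pairs
#'   (intercept, slope on log10(AL/alpha)).
#' @return an \code{ne_estimate} with \code{ne} the converted generational
#'   Ne, plus \code{nb_adj}, \code{adjusted = TRUE} and the life history.
#' @export
adjust_nb <- function(raw, AL, alpha, CVf = NULL,
                      coef_adj = c(1.103, 0.245),
                      coef_conv = c(0.485, 0.758)) {
  stopifnot(inherits(raw, "ne_estimate"), AL > alpha, alpha >= 1)
  lr <- log10(AL / alpha)
  den_adj <- coef_adj[1] - coef_adj[2] * lr
  den_conv <- coef_conv[1] + coef_conv[2] * lr
  if (den_adj <= 0 || den_conv <= 0)
    stop("adjust_nb: nonpositive adjustment denominator")
  sc <- 1 / (den_adj * den_conv)
  out <- raw
  out$nb_adj <- raw$ne / den_adj
  out$ne <- raw$ne * sc
  out$lo <- raw$lo * sc
  out$hi <- raw$hi * sc
  out$adjusted <- TRUE
  out$life_history <- list(AL = AL, alpha = alpha, CVf = CVf)
  out
}
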