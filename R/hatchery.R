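#' Linear model of a genetic metric on hatchery practices
#'
#' Ordinary least-squares (gaussian identity) fit of a restored-reef
#' genetic metric (e.g. Ne, relatedness, Ho, sMLH) on hatchery-practice
#' predictors (broodstock number, planting seasons, sex ratio, reef size).
#'
#' @param metrics data.frame, one row per restored reef.
#' @param response column name of the response.
#' @param predictors character vector of predictor column names.
#' @param family only \code{"gaussian"} is supported (the reported R2 and
#'   p are linear-model quantities).
#' @return list of class \code{practice_model}: \code{response},
#'   \code{predictors}, \code{slopes}, \code{R2}, \code{p} (overall
#'   F-test), \code{n}, \code{fit}.
#' @export
practice_model <- function(metrics, response, predictors,
                           family = "gaussian") {
  if (family != "gaussian")
    stop("only the gaussian family is supported")
  cols <- c(response, predictors)
  missing_cols <- setdiff(cols, names(metrics))
  if (length(missing_cols))
    stop("metrics table lacks column(s): ",
      paste(missing_cols, collapse = ", "))
  dat <- metrics[stats::complete.cases(metrics[, cols]), cols, drop = FALSE]
  n <- nrow(dat)
  if (n < length(predictors) + 2)
    stop("practice_model needs n >= predictors + 2 complete rows")
  X <- as.matrix(dat[, predictors, drop = FALSE])
  if (qr(cbind(1, X))$rank < ncol(X) + 1) {
    sds <- apply(X, 2, stats::sd)
    stop("rank-deficient design; collinear or constant column(s): ",
      paste(predictors[sds == 0], collapse = ", "), " (check predictors)")
  }
  fm <- stats::as.formula(paste(
    response, "~", paste(predictors, collapse = " + ")
  ))
  fit <- stats::lm(fm, data = dat)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p <- if (is.null(fstat)) NA_real_ else
    stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  structure(list(
    response = response, predictors = predictors,
    slopes = stats::coef(fit)[-1], R2 = sm$r.squared, p = unname(p),
    n = n, fit = fit
  ), class = "practice_model")
}

#' @export
print.practice_model <- function(x, ...) {
  cat(sprintf(
    "practice_model: %s ~ %s  (n = %d)\n  R2 = %.3f, p = %.4g; slopes: %s\n",
    x$response, paste(x$predictors, collapse = " + "), x$n, x$R2, x$p,
    paste(sprintf("%s = %.4g", names(x$slopes), x$slopes), collapse = ", ")
  ))
  invisible(x)
}

#' Hatchery-practice scenario grid on the simulator
#'
#' Runs planting simulations over a grid of broodstock numbers and planting
#' seasons (all else fixed): a natural source deme supplies broodstock that
#' found a restored deme over one or more seasons. Per scenario the planted
#' deme's LD-based Ne and mean Ritland relatedness are estimated, and
#' monotone-trend statistics (Spearman rho of scenario medians against each
#' practice factor) summarize the direction of the practice effects.
#'
#' @param broodstock broodstock numbers per planting season.
#' @param seasons numbers of planting seasons.
#' @param n_reps simulation replicates per scenario.
#' @param deme_N source deme size (must be >= max broodstock).
#' @param n_loci unlinked loci simulated.
#' @param offspring_per_season planted offspring per season.
#' @param sweepstakes_shape Dirichlet concentration of family sizes.
#' @param sample_n individuals sampled from the planted deme.
#' @param burnin_gens source-population burn-in.
#' @param seed master seed; each run derives its own.
#' @return list of class \code{practice_curves}: \code{results} (per run),
#'   \code{medians} (per scenario), \code{trends} (Spearman rho of medians
#'   vs broodstock and seasons).
#' @export
practice_curves <- function(broodstock = c(10, 25, 50, 100),
                            seasons = c(1, 2, 4), n_reps = 5,
                            deme_N = 200, n_loci = 800,
                            offspring_per_season = 200,
                            sweepstakes_shape = 1, sample_n = 50,
                            burnin_gens = 60, seed = 1) {
  grid <- expand.grid(broodstock = broodstock, seasons = seasons,
    rep = seq_len(n_reps))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    b <- grid$broodstock[i]; k <- grid$seasons[i]
    run_seed <- (seed * 7919 + i * 104729) %% 2147483647
    cfg <- sim_config(
      n_demes = 2, deme_N = deme_N, n_chrom = 8,
      loci_per_chrom = ceiling(n_loci / 8), mig_rate = 0.02,
      n_adaptive = 0, sel_coeff = 0, burnin_gens = burnin_gens,
      sample_n = sample_n, free_recomb = TRUE, seed = run_seed,
      hatchery = list(list(
        target_deme = 2, source_deme = 1, broodstock_n = b, n_seasons = k,
        offspring_per_season = offspring_per_season,
        sweepstakes_shape = sweepstakes_shape
      ))
    )
    sim <- simulate_metapop(cfg)
    ne <- suppressMessages(
      ld_ne(sim$genotypes, "D2", ci = FALSE, seed = run_seed)
    )
    # reference allele frequencies from the broodstock source deme:
    # within-deme frequencies would absorb the very relatedness being
    # measured into the frequency estimates
    src <- site_dosages(sim$genotypes, "D1")
    rel <- ritland_relatedness(sim$genotypes, "D2",
      freqs = colMeans(src, na.rm = TRUE) / 2)$mean
    data.frame(
      broodstock = b, seasons = k, rep = grid$rep[i],
      ne = ne$ne, relatedness = rel,
      true_nb = unname(sim$truth$true_ne["D2"]),
      pedigree_mean = {
        pr <- sim$truth$pedigree_r
        keep <- grepl("^D2_", rownames(pr))
        mean(pr[keep, keep][upper.tri(pr[keep, keep])])
      }
    )
  })
  results <- do.call(rbind, rows)
  # per-scenario medians (Ne medians over finite estimates)
  meds <- do.call(rbind, lapply(
    split(results, list(results$broodstock, results$seasons), drop = TRUE),
    function(d) data.frame(
      broodstock = d$broodstock[1], seasons = d$seasons[1],
      ne_median = stats::median(d$ne[is.finite(d$ne)]),
      rel_median = stats::median(d$relatedness)
    )
  ))
  rownames(meds) <- NULL
  sp <- function(x, y) suppressWarnings(
    stats::cor(x, y, method = "spearman", use = "complete.obs")
  )
  trends <- c(
    rho_broodstock_ne = sp(meds$broodstock, meds$ne_median),
    rho_broodstock_rel = sp(meds$broodstock, meds$rel_median),
    rho_seasons_ne = sp(meds$seasons, meds$ne_median),
    rho_seasons_rel = sp(meds$seasons, meds$rel_median)
  )
  structure(list(results = results, medians = meds, trends = trends),
    class = "practice_curves")
}

#' @export
print.practice_curves <- function(x, ...) {
  cat("practice_curves over", nrow(x$medians), "scenarios:\n")
  print(round(x$trends, 3))
  invisible(x)
}
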