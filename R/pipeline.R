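#' Pipeline configuration
#'
#' Collects the inputs (either file paths or a simulation block) and the
#' stage parameters of \code{\link{run_pipeline}}. Every stochastic stage
#' derives its seed deterministically from the master seed.
#'
#' @param vcf,site_map,sites,env,dist input file paths (VCF; sample-site
#'   map; site, environment tables; distance matrix CSV). Ignored when
#'   \code{simulate} is given.
#' @param simulate optional \code{\link{sim_config}}: generate the inputs.
#' @param out_dir output directory for report tables.
#' @param max_major_freq MAF screen threshold (major-allele frequency).
#' @param scan_q q-value threshold for scan outlier flags.
#' @param K PCs for the PCA scan (NULL = scree default).
#' @param fst_trim,fst_hmin FST-scan null-trim fraction and He floor.
#' @param n_axes,fdr_q retained RDA axes and GEA q threshold.
#' @param pcrit minor-allele screen of the Ne estimator.
#' @param span LOESS span for LD decay.
#' @param max_pairs interchromosomal pair cap for LD.
#' @param n_perm permutations for RDA/Mantel tests.
#' @param n_boot bootstrap replicates for FIS.
#' @param dapc_n_xval,pc_range,k_range clustering controls.
#' @param external_flags optional logical vector (or single-column file) of
#'   externally computed outlier flags, one per post-screen locus.
#' @param nb_adjust optional list(site=, AL=, alpha=, CVf=) applying the
#'   life-history adjustment to one single-cohort site's estimate.
#' @param seed master seed.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(vcf = NULL, site_map = NULL, sites = NULL,
                       env = NULL, dist = NULL, simulate = NULL,
                       out_dir = NULL, max_major_freq = 0.95,
                       scan_q = 0.1, K = NULL, fst_trim = 0.05,
                       fst_hmin = 0.1, n_axes = 2, fdr_q = 0.1,
                       pcrit = 0.02, span = 0.5, max_pairs = 2e6,
                       n_perm = 999, n_boot = 1000, dapc_n_xval = 50,
                       pc_range = NULL, k_range = 1:11,
                       external_flags = NULL, nb_adjust = NULL, seed = 1) {
  cfg <- as.list(environment())
  if (is.null(cfg$simulate) && is.null(cfg$vcf))
    stop("run_config: either input paths or a simulate block is required")
  class(cfg) <- "run_config"
  cfg
}

stage_seed <- function(seed, k) (seed * 1009 + k * 7919) %% 2147483647

pipeline_log <- function(...) message("[reefgen] ", ...)

#' Run the full analysis pipeline
#'
#' Stages, in study order: data acquisition (simulation or files) ->
#' MAF screen -> differentiation outlier scans (+ optional external flags)
#' -> RDA genotype-environment outliers on the full screened set ->
#' neutral/outlier/adaptive partition -> LD thinning of the neutral set ->
#' per-site diversity, relatedness, sMLH and LD-Ne on the thinned neutral
#' set -> pairwise FST, Mantel isolation-by-distance and clustering on the
#' thinned neutral set -> environment/geography variance partitioning on
#' the neutral (and, separately, adaptive) sets -> hatchery-practice
#' models. Every table is returned and, when \code{out_dir} is set, written
#' as CSV along with the config and seed.
#'
#' @param cfg a \code{\link{run_config}}.
#' @return list of class \code{reefgen_report} with the stage outputs.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- Sys.time()
  pipeline_log("master seed = ", cfg$seed)

  if (!is.null(cfg$simulate)) {
    pipeline_log("stage simulate")
    sim <- simulate_metapop(cfg$simulate)
    g <- sim$genotypes; sites_tab <- sim$sites; env_tab <- sim$env
    dist_mat <- sim$dist; truth <- sim$truth
  } else {
    pipeline_log("stage read: ", cfg$vcf)
    g <- read_vcf(cfg$vcf, cfg$site_map)
    sites_tab <- read_site_table(cfg$sites)
    env_tab <- read_env_table(cfg$env)
    dist_mat <- read_dist_matrix(cfg$dist)
    truth <- NULL
  }
  pipeline_log("input: ", n_ind(g), " individuals x ", n_loci(g), " SNPs")

  pipeline_log("stage screen: max major-allele freq ", cfg$max_major_freq)
  g <- screen_maf(g, cfg$max_major_freq)
  pipeline_log("post-screen: ", n_loci(g), " SNPs")

  pipeline_log("stage scan")
  pca_res <- pca_scan(g, K = cfg$K, seed = stage_seed(cfg$seed, 2))
  fst_res <- tryCatch(fst_scan(g, trim = cfg$fst_trim, Hmin = cfg$fst_hmin),
    error = function(e) {
      pipeline_log("fst_scan skipped: ", conditionMessage(e))
      NULL
    })
  flags <- list(pca = !is.na(pca_res$q) & pca_res$q < cfg$scan_q)
  if (!is.null(fst_res))
    flags$fst <- !is.na(fst_res$q) & fst_res$q < cfg$scan_q
  external <- cfg$external_flags
  if (is.character(external) && length(external) == 1L)
    external <- as.logical(read_table_auto(external)[[1]])

  pipeline_log("stage gea")
  env_vars <- setdiff(
    names(env_tab)[vapply(env_tab, is.numeric, logical(1))], "site"
  )
  max_vars <- nrow(env_tab) - 2
  if (length(env_vars) > max_vars) {
    pipeline_log("too few sites for ", length(env_vars),
      " env variables; keeping the first ", max_vars)
    env_tab <- env_tab[, c("site", env_vars[seq_len(max_vars)])]
  }
  env_scr <- vif_screen(env_tab)
  pipeline_log("env variables retained: ",
    paste(setdiff(names(env_scr), "site"), collapse = ", "))
  env_ind <- broadcast_to_ind(env_scr, sites_of(g))
  fit <- rda_fit(g, env_ind, n_perm = cfg$n_perm,
    blocks = sites_of(g), seed = stage_seed(cfg$seed, 3), axis_p = TRUE)
  gea <- gea_outliers(fit, n_axes = min(cfg$n_axes, length(fit$eig)),
    fdr_q = cfg$fdr_q, seed = stage_seed(cfg$seed, 4))

  pipeline_log("stage partition")
  part <- combine_partition(flags, rda_flags = gea$flagged,
    external = external)
  pipeline_log(length(part$neutral), " neutral / ",
    length(part$outlier_union), " outlier / ",
    length(part$adaptive_intersection), " adaptive")

  pipeline_log("stage thin (neutral set)")
  g_neutral <- subset_genotypes(g, loci = part$neutral)
  ld <- pairwise_r2(g_neutral, max_pairs = cfg$max_pairs,
    seed = stage_seed(cfg$seed, 5))
  plan <- tryCatch({
    crit <- critical_r2(ld)
    thinning_plan(ld, crit, span = cfg$span)
  }, error = function(e) {
    pipeline_log("thinning skipped: ", conditionMessage(e))
    NULL
  })
  g_thin <- if (is.null(plan)) g_neutral else thin(g_neutral, plan)
  pipeline_log("thinned neutral set: ", n_loci(g_thin), " SNPs")

  pipeline_log("stage diversity")
  div <- diversity_summary(g_thin, n_boot = cfg$n_boot,
    seed = stage_seed(cfg$seed, 6))
  smlh_vals <- smlh(g_thin)

  pipeline_log("stage ne")
  ne_tab <- do.call(rbind, lapply(unique(sites_of(g_thin)), function(s) {
    est <- tryCatch(
      suppressMessages(ld_ne(g_thin, s, pcrit = cfg$pcrit,
        seed = stage_seed(cfg$seed, 7))),
      error = function(e) NULL
    )
    if (is.null(est)) return(NULL)
    if (!is.null(cfg$nb_adjust) && identical(cfg$nb_adjust$site, s)) {
      est <- adjust_nb(est, AL = cfg$nb_adjust$AL,
        alpha = cfg$nb_adjust$alpha, CVf = cfg$nb_adjust$CVf)
    }
    data.frame(site = s, Ne = est$ne, Ne_lo = est$lo, Ne_hi = est$hi,
      r2 = est$r2, S = est$S, adjusted = est$adjusted,
      stringsAsFactors = FALSE)
  }))

  pipeline_log("stage structure")
  fst_mat <- pairwise_fst(g_thin)
  ibd <- tryCatch(
    mantel_ibd(fst_mat, dist_mat, n_perm = cfg$n_perm,
      seed = stage_seed(cfg$seed, 8)),
    error = function(e) {
      pipeline_log("mantel skipped: ", conditionMessage(e)); NULL
    })
  dapc_res <- dapc(g_thin, pc_range = cfg$pc_range,
    n_xval = cfg$dapc_n_xval, seed = stage_seed(cfg$seed, 9))
  km <- kmeans_bic(g_thin, k_range = cfg$k_range,
    seed = stage_seed(cfg$seed, 10))

  pipeline_log("stage varpart")
  pcnm_mat <- pcnm_axes(dist_mat)
  n_keep <- min(2, ncol(pcnm_mat))
  space_ind <- broadcast_to_ind(
    data.frame(site = rownames(pcnm_mat),
      pcnm_mat[, seq_len(n_keep), drop = FALSE]),
    sites_of(g_thin)
  )
  env_thin <- broadcast_to_ind(env_scr, sites_of(g_thin))
  vp_neutral <- variance_partition(g_thin, env_thin, space_ind,
    n_perm = cfg$n_perm, blocks = sites_of(g_thin),
    seed = stage_seed(cfg$seed, 11))
  vp_adaptive <- NULL
  if (length(part$adaptive_intersection) >= 2) {
    g_adapt <- subset_genotypes(g, loci = part$adaptive_intersection)
    vp_adaptive <- variance_partition(
      g_adapt,
      broadcast_to_ind(env_scr, sites_of(g_adapt)),
      broadcast_to_ind(
        data.frame(site = rownames(pcnm_mat),
          pcnm_mat[, seq_len(n_keep), drop = FALSE]),
        sites_of(g_adapt)
      ),
      n_perm = cfg$n_perm, blocks = sites_of(g_adapt),
      seed = stage_seed(cfg$seed, 12)
    )
  }
  terms_tab <- rda_terms(g_thin, cbind(env_thin, space_ind),
    n_perm = min(cfg$n_perm, 199), blocks = sites_of(g_thin),
    seed = stage_seed(cfg$seed, 13))

  pipeline_log("stage practices")
  metrics <- merge(div, sites_tab, by = "site")
  if (!is.null(ne_tab)) metrics <- merge(metrics, ne_tab, by = "site")
  practices <- NULL
  restored <- metrics[metrics$type == "restored", , drop = FALSE]
  if (nrow(restored) >= 3) {
    practices <- list()
    for (resp in c("Ne", "relatedness", "Ho")) {
      for (pred in c("broodstock_n", "planting_seasons")) {
        ok <- sum(stats::complete.cases(restored[, c(resp, pred)]))
        if (ok >= 3 && stats::sd(restored[[pred]], na.rm = TRUE) > 0) {
          practices[[paste(resp, pred, sep = "~")]] <-
            tryCatch(practice_model(restored, resp, pred),
              error = function(e) NULL)
        }
      }
    }
  }

  # per-SNP results table
  snp_tab <- g$loci[, c("chrom", "pos", "id")]
  snp_tab$pca_p <- pca_res$p
  snp_tab$pca_q <- pca_res$q
  if (!is.null(fst_res)) {
    snp_tab$fst <- fst_res$fst
    snp_tab$fst_p <- fst_res$p
    snp_tab$fst_q <- fst_res$q
  }
  snp_tab$rda_D2 <- gea$D2
  snp_tab$rda_p <- gea$p
  snp_tab$rda_q <- gea$q
  snp_tab$assigned_var <- gea$assigned_var
  snp_tab$class <- part$class

  report <- structure(list(
    config = cfg, seed = cfg$seed,
    n_input = n_ind(g), snp_counts = c(
      total = n_loci(g), neutral = length(part$neutral),
      outlier_union = length(part$outlier_union),
      adaptive = length(part$adaptive_intersection),
      thinned_neutral = n_loci(g_thin)
    ),
    snp_table = snp_tab, partition = part,
    pca_lambda = attr(pca_res, "lambda"),
    rda = fit, gea = gea, thinning = plan,
    diversity = div, smlh = smlh_vals, ne = ne_tab,
    fst = fst_mat, ibd = ibd, dapc = dapc_res, kmeans = km,
    varpart_neutral = vp_neutral, varpart_adaptive = vp_adaptive,
    rda_terms = terms_tab,
    practices = practices, truth = truth,
    elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "reefgen_report")

  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.reefgen_report <- function(x, ...) {
  cat("reefgen_report (", round(x$elapsed, 1), "s )\n", sep = "")
  cat("  SNPs:", paste(names(x$snp_counts), x$snp_counts, sep = "=",
    collapse = ", "), "\n")
  cat("  sites:", nrow(x$diversity), "; DAPC PCs:",
    x$dapc$n_pcs_retained, "; k-means best k:", x$kmeans$best_k, "\n")
  if (!is.null(x$ibd))
    cat(sprintf("  IBD: r = %.3f, p = %.4g\n", x$ibd$r, x$ibd$p))
  invisible(x)
}

#' Write a report bundle as CSV/JSON files
#' @param report a \code{reefgen_report}.
#' @param out_dir directory (created if absent).
#' @return \code{out_dir}, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) utils::write.csv(df,
    file.path(out_dir, name), row.names = FALSE)
  w(report$snp_table, "snp_results.csv")
  w(report$diversity, "diversity.csv")
  if (!is.null(report$ne)) w(report$ne, "ne.csv")
  utils::write.csv(as.data.frame(unclass(report$fst)),
    file.path(out_dir, "fst_matrix.csv"))
  w(report$varpart_neutral, "varpart_neutral.csv")
  if (!is.null(report$varpart_adaptive))
    w(report$varpart_adaptive, "varpart_adaptive.csv")
  w(report$rda_terms, "rda_terms.csv")
  w(data.frame(k = report$kmeans$bic_curve$k,
    BIC = report$kmeans$bic_curve$BIC), "bic_curve.csv")
  w(data.frame(id = names(report$smlh), smlh = report$smlh), "smlh.csv")
  # Manhattan-style plot data for the GEA
  man <- report$snp_table[, c("chrom", "pos", "rda_p", "assigned_var")]
  man$neglog10p <- -log10(man$rda_p)
  w(man, "gea_manhattan.csv")
  if (!is.null(report$ibd))
    jsonlite::write_json(report$ibd, file.path(out_dir, "mantel_ibd.json"),
      auto_unbox = TRUE, digits = NA)
  cfg <- report$config
  cfg$simulate <- if (!is.null(cfg$simulate)) unclass(cfg$simulate)
  jsonlite::write_json(
    lapply(unclass(cfg), function(x) if (is.function(x)) NULL else x),
    file.path(out_dir, "config.json"),
    auto_unbox = TRUE, digits = NA, null = "null", force = TRUE
  )
  invisible(out_dir)
}
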