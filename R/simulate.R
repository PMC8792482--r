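#' Configuration for the forward-time metapopulation simulator
#'
#' Demes sit on a linear environmental (salinity) gradient. Each generation
#' applies viability selection at the adaptive loci, migration between demes,
#' and Wright-Fisher reproduction with intrachromosomal recombination.
#' Hatchery planting events found a target deme from a finite broodstock
#' drawn from a source deme, with Dirichlet-multinomial family sizes
#' (small \code{sweepstakes_shape} = sweepstakes reproduction).
#'
#' @param n_demes number of demes.
#' @param deme_N census (= ideal effective) size per deme.
#' @param n_chrom number of chromosomes.
#' @param loci_per_chrom SNPs per chromosome.
#' @param chrom_length chromosome length in bp.
#' @param mig_rate per-generation migration rate m (0..0.5).
#' @param migration_model \code{"stepping_stone"} (neighbours exchange m/2
#'   each side) or \code{"island"} (migrant pool from all other demes).
#' @param n_adaptive number of environment-associated loci.
#' @param sel_coeff selection coefficient s in the multiplicative fitness
#'   \eqn{\prod_l (1 + s_l a_l z_d)} with \eqn{a_l \in \{-1,0,1\}} the centered
#'   genotype and \eqn{z_d} the standardized deme salinity.
#' @param sel_jitter multiplicative half-width of per-locus effect-size
#'   variation: \eqn{s_l = s (1 + U(-j, j))}. 0 (default) gives equal
#'   effects; positive values give a mix of weak and strong loci, as
#'   polygenic salinity tolerance would.
#' @param env_gradient per-deme mean salinity (PSU); default linear 8..28.
#' @param burnin_gens burn-in generations before sampling/planting.
#' @param sample_n individuals sampled per deme for output.
#' @param recomb_rate crossover probability per bp between adjacent loci
#'   (capped at 0.5); default 1e-8 (1 cM/Mb).
#' @param free_recomb if TRUE all loci segregate independently (c = 0.5),
#'   the "unlinked loci" regime used when validating the LD Ne estimator.
#' @param missing_rate fraction of genotype calls masked to NA in the output.
#' @param deme_spacing_km water distance between adjacent demes.
#' @param hatchery list of planting events, each a list with elements
#'   \code{target_deme}, \code{source_deme}, \code{broodstock_n},
#'   \code{n_seasons}, \code{offspring_per_season}, \code{sweepstakes_shape}.
#' @param seed integer RNG seed; a single stream drives every draw, so one
#'   seed reproduces the whole run byte-for-byte.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n_demes = 9, deme_N = 100, n_chrom = 10,
                       loci_per_chrom = 100, chrom_length = 5e7,
                       mig_rate = 0.05,
                       migration_model = c("stepping_stone", "island"),
                       n_adaptive = 25, sel_coeff = 0.15,
                       sel_jitter = 0,
                       env_gradient = NULL, burnin_gens = 150,
                       sample_n = 40, recomb_rate = 1e-8,
                       free_recomb = FALSE, missing_rate = 0,
                       deme_spacing_km = 20, hatchery = list(), seed = 1) {
  migration_model <- match.arg(migration_model)
  if (is.null(env_gradient)) {
    env_gradient <- if (n_demes > 1) seq(8, 28, length.out = n_demes) else 18
  }
  cfg <- list(
    n_demes = n_demes, deme_N = deme_N, n_chrom = n_chrom,
    loci_per_chrom = loci_per_chrom, chrom_length = chrom_length,
    mig_rate = mig_rate, migration_model = migration_model,
    n_adaptive = n_adaptive, sel_coeff = sel_coeff,
    sel_jitter = sel_jitter,
    env_gradient = env_gradient, burnin_gens = burnin_gens,
    sample_n = sample_n, recomb_rate = recomb_rate,
    free_recomb = free_recomb, missing_rate = missing_rate,
    deme_spacing_km = deme_spacing_km, hatchery = hatchery, seed = seed
  )
  stopifnot(
    mig_rate >= 0, mig_rate <= 0.5,
    n_adaptive <= n_chrom * loci_per_chrom,
    n_demes >= 1, deme_N >= 2, n_chrom >= 1, loci_per_chrom >= 1,
    burnin_gens >= 1, sample_n >= 2,
    length(env_gradient) == n_demes
  )
  for (ev in hatchery) {
    stopifnot(all(c(
      "target_deme", "source_deme", "broodstock_n", "n_seasons",
      "offspring_per_season"
    ) %in% names(ev)))
    if (ev$broodstock_n > deme_N)
      stop("hatchery broodstock_n exceeds deme_N")
  }
  class(cfg) <- "sim_config"
  cfg
}

# One meiosis per row: recombine haplotype matrices H1/H2 (n x L).
# cross_p[l] is the crossover probability between locus l-1 and l
# (0.5 across chromosome boundaries).
recombine_gametes <- function(H1, H2, cross_p, free_recomb = FALSE) {
  n <- nrow(H1)
  L <- ncol(H1)
  if (free_recomb) {
    choose <- matrix(sample(c(0L, 1L), n * L, replace = TRUE), n, L)
  } else {
    choose <- matrix(0L, n, L)
    choose[, 1] <- sample(c(0L, 1L), n, replace = TRUE)
    if (L > 1) {
      sw <- matrix(
        stats::rbinom(n * (L - 1), 1L, rep(cross_p[-1], each = n)), n, L - 1
      )
      for (l in 2:L) choose[, l] <- bitwXor(choose[, l - 1L], sw[, l - 1L])
    }
  }
  H1 * (1L - choose) + H2 * choose
}

# Multiplicative viability fitness of a deme's individuals.
deme_fitness <- function(hapA, hapB, adaptive_idx, s, z) {
  if (length(adaptive_idx) == 0L || all(s == 0) || z == 0)
    return(rep(1, nrow(hapA)))
  a <- hapA[, adaptive_idx, drop = FALSE] + hapB[, adaptive_idx, drop = FALSE] - 1L
  sz <- rep_len(s, length(adaptive_idx)) * z
  exp(rowSums(log(pmax(1 + sweep(a, 2, sz, "*"), 1e-9))))
}

# Source-deme distribution for one parent draw of an offspring born in d.
migration_probs <- function(d, n_demes, m, model) {
  p <- rep(0, n_demes)
  if (n_demes == 1L) {
    p[d] <- 1
  } else if (model == "island") {
    p[] <- m / (n_demes - 1)
    p[d] <- 1 - m
  } else {
    if (d > 1) p[d - 1] <- m / 2
    if (d < n_demes) p[d + 1] <- m / 2
    p[d] <- 1 - sum(p)
  }
  p
}

#' Run the forward-time simulation
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return a list of class \code{reefgen_sim} with elements
#'   \code{genotypes} (a \code{\link{genotype_matrix}} of the sampled final
#'   generation), \code{sites}, \code{env}, \code{dist} (per-site metadata,
#'   environmental table, water-distance matrix), \code{truth}
#'   (\code{sim_truth}: per-deme true Ne, adaptive locus indices and effects,
#'   one-generation pedigree relatedness of the sampled individuals, and the
#'   planting log), and \code{config}.
#' @export
simulate_metapop <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  D <- cfg$n_demes
  N <- cfg$deme_N
  L <- cfg$n_chrom * cfg$loci_per_chrom

  # locus map
  chrom <- rep(paste0("chr", seq_len(cfg$n_chrom)), each = cfg$loci_per_chrom)
  pos <- unlist(lapply(seq_len(cfg$n_chrom), function(i) {
    sort(sample.int(cfg$chrom_length, cfg$loci_per_chrom))
  }))
  cross_p <- c(0, pmin(0.5, cfg$recomb_rate * diff(pos)))
  cross_p[c(0, diff(match(chrom, unique(chrom)))) != 0] <- 0.5

  # standing variation at burn-in start
  p0 <- stats::rbeta(L, 0.5, 0.5)
  pop <- lapply(seq_len(D), function(d) {
    list(
      hapA = matrix(stats::rbinom(N * L, 1L, rep(p0, each = N)), N, L),
      hapB = matrix(stats::rbinom(N * L, 1L, rep(p0, each = N)), N, L),
      mother = rep(NA_character_, N), father = rep(NA_character_, N)
    )
  })

  adaptive_idx <- if (cfg$n_adaptive > 0) sort(sample.int(L, cfg$n_adaptive)) else integer(0)
  sel <- if (length(adaptive_idx)) cfg$sel_coeff *
    (1 + stats::runif(length(adaptive_idx), -cfg$sel_jitter, cfg$sel_jitter))
  else numeric(0)
  z <- if (D > 1) as.numeric(scale(cfg$env_gradient)) else 0

  advance <- function(pop) {
    # fitness-weighted parent sampling: marginal per-locus selection is
    # identical to viability selection with relative fitness w, without
    # the survivor-count collapse a Bernoulli accept/reject scheme shows
    # when many strong loci make max(w) an extreme outlier
    wts <- lapply(seq_len(D), function(d) {
      deme_fitness(pop[[d]]$hapA, pop[[d]]$hapB, adaptive_idx, sel,
        if (length(z) > 1) z[d] else z)
    })
    lapply(seq_len(D), function(d) {
      pr <- migration_probs(d, D, cfg$mig_rate, cfg$migration_model)
      md <- sample.int(D, N, replace = TRUE, prob = pr)
      fd <- sample.int(D, N, replace = TRUE, prob = pr)
      mi <- integer(N); fi <- integer(N)
      for (s in unique(c(md, fd))) {
        k <- md == s
        if (any(k)) mi[k] <- sample.int(N, sum(k), replace = TRUE,
          prob = wts[[s]])
        k <- fd == s
        if (any(k)) fi[k] <- sample.int(N, sum(k), replace = TRUE,
          prob = wts[[s]])
      }
      M1 <- matrix(0L, N, L); M2 <- M1; F1 <- M1; F2 <- M1
      for (s in unique(c(md, fd))) {
        k <- which(md == s)
        if (length(k)) {
          M1[k, ] <- pop[[s]]$hapA[mi[k], , drop = FALSE]
          M2[k, ] <- pop[[s]]$hapB[mi[k], , drop = FALSE]
        }
        k <- which(fd == s)
        if (length(k)) {
          F1[k, ] <- pop[[s]]$hapA[fi[k], , drop = FALSE]
          F2[k, ] <- pop[[s]]$hapB[fi[k], , drop = FALSE]
        }
      }
      list(
        hapA = recombine_gametes(M1, M2, cross_p, cfg$free_recomb),
        hapB = recombine_gametes(F1, F2, cross_p, cfg$free_recomb),
        mother = paste0(md, ":", mi), father = paste0(fd, ":", fi)
      )
    })
  }

  for (g in seq_len(cfg$burnin_gens)) pop <- advance(pop)

  # hatchery planting: each season advances the metapopulation one
  # generation (a spawning year), draws fresh broodstock from the source
  # deme and spawns offspring with Dirichlet-multinomial family sizes.
  planting_log <- list()
  true_ne <- rep(cfg$deme_N, D)
  names(true_ne) <- paste0("D", seq_len(D))
  planted <- rep(FALSE, D)
  seasons <- rep(0L, D)
  brood_used <- rep(NA_real_, D)
  for (ev in cfg$hatchery) {
    pool_A <- NULL; pool_B <- NULL; mothers <- character(0); fathers <- character(0)
    nb_seasons <- numeric(0)
    for (season in seq_len(ev$n_seasons)) {
      if (season > 1) pop <- advance(pop)
      src <- pop[[ev$source_deme]]
      brood <- sample.int(N, ev$broodstock_n)
      shape <- if (is.null(ev$sweepstakes_shape)) 1 else ev$sweepstakes_shape
      w <- if (is.infinite(shape)) rep(1, ev$broodstock_n) else
        stats::rgamma(ev$broodstock_n, shape = shape, rate = 1)
      if (all(w == 0)) w[] <- 1
      n_off <- ev$offspring_per_season
      mo <- sample(brood, n_off, replace = TRUE, prob = w)
      fa <- sample(brood, n_off, replace = TRUE, prob = w)
      if (ev$broodstock_n >= 2) {
        while (any(bad <- fa == mo))
          fa[bad] <- sample(brood, sum(bad), replace = TRUE, prob = w)
      }
      # realized family (gamete) sizes -> inbreeding Ne of the season
      k <- tabulate(match(c(mo, fa), brood), nbins = ev$broodstock_n)
      kbar <- mean(k)
      vk <- stats::var(k)
      nb_seasons <- c(nb_seasons,
        (ev$broodstock_n * kbar - 1) / (kbar - 1 + vk / kbar))
      eggs <- recombine_gametes(
        src$hapA[mo, , drop = FALSE], src$hapB[mo, , drop = FALSE],
        cross_p, cfg$free_recomb
      )
      sperm <- recombine_gametes(
        src$hapA[fa, , drop = FALSE], src$hapB[fa, , drop = FALSE],
        cross_p, cfg$free_recomb
      )
      pool_A <- rbind(pool_A, eggs)
      pool_B <- rbind(pool_B, sperm)
      mothers <- c(mothers, paste0("b", season, ":", mo))
      fathers <- c(fathers, paste0("b", season, ":", fa))
      planting_log[[length(planting_log) + 1]] <- list(
        target_deme = ev$target_deme, season = season,
        broodstock_ids = brood, nb_season = nb_seasons[length(nb_seasons)]
      )
    }
    pop[[ev$target_deme]] <- list(
      hapA = pool_A, hapB = pool_B, mother = mothers, father = fathers
    )
    planted[ev$target_deme] <- TRUE
    seasons[ev$target_deme] <- ev$n_seasons
    brood_used[ev$target_deme] <- ev$broodstock_n
    true_ne[ev$target_deme] <- sum(nb_seasons)
  }

  # sample the final generation
  dos <- NULL; ind_id <- character(0); ind_site <- character(0)
  mother <- character(0); father <- character(0)
  for (d in seq_len(D)) {
    avail <- nrow(pop[[d]]$hapA)
    take <- sample.int(avail, min(cfg$sample_n, avail))
    dos <- rbind(dos, pop[[d]]$hapA[take, , drop = FALSE] +
      pop[[d]]$hapB[take, , drop = FALSE])
    ind_id <- c(ind_id, paste0("D", d, "_", seq_along(take)))
    ind_site <- c(ind_site, rep(paste0("D", d), length(take)))
    mother <- c(mother, paste0(d, "|", pop[[d]]$mother[take]))
    father <- c(father, paste0(d, "|", pop[[d]]$father[take]))
  }
  if (cfg$missing_rate > 0) {
    mask <- matrix(
      stats::runif(length(dos)) < cfg$missing_rate, nrow(dos), ncol(dos)
    )
    dos[mask] <- NA_integer_
  }
  resim <- FALSE
  p_final <- colMeans(dos, na.rm = TRUE) / 2
  if (all(p_final %in% c(0, 1) | is.na(p_final))) {
    warning("all loci fixed before sampling; set resimulate flag")
    resim <- TRUE
  }

  loci <- data.frame(
    chrom = chrom, pos = pos, id = paste0(chrom, ":", pos),
    ref = "A", alt = "T", stringsAsFactors = FALSE
  )
  genotypes <- genotype_matrix(
    dos, loci,
    data.frame(id = ind_id, site = ind_site, stringsAsFactors = FALSE)
  )

  site_names <- paste0("D", seq_len(D))
  sitefr <- data.frame(
    site = site_names,
    type = ifelse(planted, "restored", "natural"),
    lat = 37 + 0.15 * (seq_len(D) - 1), lon = -76,
    planting_seasons = seasons,
    broodstock_n = brood_used,
    sex_ratio = NA_real_, reef_size = NA_real_,
    stringsAsFactors = FALSE
  )
  env <- data.frame(
    site = site_names,
    mean_salinity = cfg$env_gradient,
    min_salinity = cfg$env_gradient - 3 + stats::rnorm(D, 0, 0.5),
    mean_wtemp = 16 + stats::rnorm(D, 0, 1.5),
    min_wtemp = 4 + stats::rnorm(D, 0, 1),
    min_DO = 5 + stats::rnorm(D, 0, 0.8),
    mean_pH = 7.9 + stats::rnorm(D, 0, 0.12),
    stringsAsFactors = FALSE
  )
  dmat <- cfg$deme_spacing_km * abs(outer(seq_len(D), seq_len(D), "-"))
  dimnames(dmat) <- list(site_names, site_names)

  # one-generation pedigree relatedness of the sampled individuals:
  # r = (shared parent slots) / 4 (full sibs 0.5, half sibs 0.25)
  nS <- length(ind_id)
  ped <- (outer(mother, mother, "==") + outer(mother, father, "==") +
    outer(father, mother, "==") + outer(father, father, "==")) / 4
  diag(ped) <- 1
  dimnames(ped) <- list(ind_id, ind_id)

  truth <- structure(list(
    true_ne = true_ne,
    adaptive_loci = data.frame(
      locus = adaptive_idx,
      id = loci$id[adaptive_idx],
      env_var = if (length(adaptive_idx)) "mean_salinity" else character(0),
      s = sel,
      stringsAsFactors = FALSE
    ),
    pedigree_r = ped,
    planting_log = planting_log,
    init_freq = p0
  ), class = "sim_truth")

  structure(
    list(
      genotypes = genotypes, sites = sitefr, env = env, dist = dmat,
      truth = truth, config = cfg, resimulate = resim
    ),
    class = "reefgen_sim"
  )
}

#' @export
print.reefgen_sim <- function(x, ...) {
  cat("reefgen_sim:", x$config$n_demes, "demes,",
    n_ind(x$genotypes), "sampled individuals,",
    n_loci(x$genotypes), "SNPs\n")
  invisible(x)
}

#' Deterministic hash of a simulation configuration
#' @param cfg a \code{sim_config}
#' @return md5 hex string.
#' @export
config_hash <- function(cfg) {
  canon <- function(x) {
    if (is.list(x)) {
      paste0("{", paste(names(x), vapply(x, canon, character(1)),
        sep = "=", collapse = ";"), "}")
    } else if (is.numeric(x)) {
      paste(format(as.numeric(x), digits = 15, trim = TRUE,
        scientific = FALSE), collapse = ",")
    } else {
      paste(as.character(x), collapse = ",")
    }
  }
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(canon(unclass(cfg)), tf)
  unname(tools::md5sum(tf))
}

#' Serialize simulator ground truth to JSON
#'
#' The seed, the full configuration, and a configuration hash are embedded
#' so a truth file is self-describing; \code{\link{read_truth}} restores it.
#'
#' @param truth a \code{sim_truth} (from \code{\link{simulate_metapop}}).
#' @param cfg the \code{sim_config} that produced it.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
truth_report <- function(truth, cfg, path) {
  payload <- list(
    seed = cfg$seed,
    config = unclass(cfg),
    config_hash = config_hash(cfg),
    true_ne = as.list(truth$true_ne),
    adaptive_loci = as.list(truth$adaptive_loci),
    pedigree_r = truth$pedigree_r,
    planting_log = truth$planting_log,
    init_freq = truth$init_freq
  )
  jsonlite::write_json(payload, path,
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  invisible(path)
}

#' Read a truth report back
#' @param path a JSON file written by \code{\link{truth_report}}.
#' @return list with the same fields; the embedded hash is checked against
#'   a recomputation from the embedded config.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path,
    simplifyVector = TRUE, simplifyDataFrame = FALSE
  )
  required <- c("seed", "config", "config_hash", "true_ne", "adaptive_loci")
  if (!all(required %in% names(x)))
    stop("truth file missing fields: ",
      paste(setdiff(required, names(x)), collapse = ", "))
  x$adaptive_loci <- as.data.frame(x$adaptive_loci,
    stringsAsFactors = FALSE)
  cfg <- x$config
  class(cfg) <- "sim_config"
  if (!identical(unname(config_hash(cfg)), x$config_hash))
    warning("embedded config hash does not match recomputation")
  x
}

#' Simulate genotype pairs of known relatedness
#'
#' Generates independent loci in Hardy-Weinberg proportions at allele
#' frequencies drawn uniformly from \code{maf_range}, then builds pairs that
#' are unrelated, parent-offspring (one allele passed per locus), or full
#' sibs. Used to calibrate the relatedness estimator.
#'
#' @param n_pairs number of pairs (output has 2*n_pairs individuals).
#' @param n_loci number of independent loci.
#' @param relationship one of "unrelated", "parent_offspring", "full_sib".
#' @param maf_range range of alternate-allele frequencies.
#' @param seed RNG seed.
#' @return list with \code{genotypes} (a \code{genotype_matrix}, single site
#'   "P", pair k = individuals 2k-1, 2k) and \code{freq} (the true allele
#'   frequencies).
#' @export
simulate_pairs <- function(n_pairs, n_loci,
                           relationship = c(
                             "unrelated", "parent_offspring", "full_sib"
                           ),
                           maf_range = c(0.1, 0.5), seed = 1) {
  relationship <- match.arg(relationship)
  set.seed(seed)
  p <- stats::runif(n_loci, maf_range[1], maf_range[2])
  draw_hap <- function(n) matrix(
    stats::rbinom(n * n_loci, 1L, rep(p, each = n)), n, n_loci
  )
  n <- n_pairs
  a1 <- draw_hap(n); a2 <- draw_hap(n)    # individual A
  if (relationship == "unrelated") {
    b1 <- draw_hap(n); b2 <- draw_hap(n)
  } else if (relationship == "parent_offspring") {
    pass <- matrix(stats::runif(n * n_loci) < 0.5, n, n_loci)
    b1 <- ifelse(pass, a1, a2)            # inherited from A
    b2 <- draw_hap(n)                     # from the other (random) parent
  } else {
    m1 <- a1; m2 <- a2                    # shared mother
    f1 <- draw_hap(n); f2 <- draw_hap(n)  # shared father
    seg <- function(h1, h2) {
      s <- matrix(stats::runif(n * n_loci) < 0.5, n, n_loci)
      ifelse(s, h1, h2)
    }
    a1 <- seg(m1, m2); a2 <- seg(f1, f2)
    b1 <- seg(m1, m2); b2 <- seg(f1, f2)
  }
  dos <- matrix(0L, 2 * n, n_loci)
  dos[seq(1, 2 * n, by = 2), ] <- a1 + a2
  dos[seq(2, 2 * n, by = 2), ] <- b1 + b2
  loci <- data.frame(
    chrom = "chr1", pos = seq_len(n_loci),
    id = paste0("L", seq_len(n_loci)), stringsAsFactors = FALSE
  )
  ind <- data.frame(
    id = paste0("P", rep(seq_len(n), each = 2), c("a", "b")),
    site = "P", stringsAsFactors = FALSE
  )
  list(genotypes = genotype_matrix(dos, loci, ind), freq = p)
}
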