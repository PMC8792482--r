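#' Construct a genotype matrix object
#'
#' The central container for all analyses: a matrix of alternate-allele
#' dosages (individuals x biallelic loci, values 0/1/2 or \code{NA} for
#' missing) together with locus coordinates and per-individual site labels.
#' Loci are re-sorted by (chromosome, position) so that downstream distance
#' based operations (LD decay, thinning) are deterministic.
#'
#' @param dosages integer matrix, individuals in rows, loci in columns;
#'   entries in \{0, 1, 2, NA\}.
#' @param loci data.frame with columns \code{chrom}, \code{pos} (1-based bp),
#'   \code{id}, and optionally \code{ref}, \code{alt}.
#' @param individuals data.frame with columns \code{id} and \code{site}.
#' @return An object of class \code{genotype_matrix}: a list with elements
#'   \code{dosages}, \code{loci}, \code{individuals}.
#' @export
genotype_matrix <- function(dosages, loci, individuals) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  stopifnot(
    nrow(loci) == ncol(dosages),
    nrow(individuals) == nrow(dosages),
    all(c("chrom", "pos", "id") %in% names(loci)),
    all(c("id", "site") %in% names(individuals))
  )
  if (any(loci$pos < 1)) stop("locus positions must be >= 1")
  bad <- !(dosages %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  if (anyDuplicated(loci[, c("chrom", "pos")]))
    stop("duplicate (chrom, pos) locus coordinates")
  ord <- order(loci$chrom, loci$pos)
  loci <- loci[ord, , drop = FALSE]
  dosages <- dosages[, ord, drop = FALSE]
  rownames(loci) <- NULL
  dimnames(dosages) <- list(individuals$id, loci$id)
  structure(
    list(dosages = dosages, loci = loci, individuals = individuals),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(
    "genotype_matrix:", nrow(x$dosages), "individuals x",
    ncol(x$dosages), "biallelic SNPs on",
    length(unique(x$loci$chrom)), "chromosome(s);",
    length(unique(x$individuals$site)), "site(s)\n"
  )
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missingness: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Number of loci / individuals
#' @param g a \code{genotype_matrix}
#' @return integer count.
#' @export
n_loci <- function(g) ncol(g$dosages)

#' @rdname n_loci
#' @export
n_ind <- function(g) nrow(g$dosages)

#' Site labels in individual order
#' @param g a \code{genotype_matrix}
#' @return character vector, one entry per individual.
#' @export
sites_of <- function(g) g$individuals$site

#' Subset a genotype matrix
#'
#' @param g a \code{genotype_matrix}
#' @param ind logical/integer index over individuals (default all)
#' @param loci logical/integer index over loci (default all)
#' @return a \code{genotype_matrix} (locus order preserved).
#' @export
subset_genotypes <- function(g, ind = NULL, loci = NULL) {
  if (is.null(ind)) ind <- seq_len(n_ind(g))
  if (is.null(loci)) loci <- seq_len(n_loci(g))
  genotype_matrix(
    g$dosages[ind, loci, drop = FALSE],
    g$loci[loci, , drop = FALSE],
    g$individuals[ind, , drop = FALSE]
  )
}

#' Read a VCF into a genotype matrix
#'
#' Only the GT field is used. Multiallelic records, non-SNP records
#' (indels), and loci with call rate below \code{min_call_rate} are dropped,
#' with counts reported via \code{message()}. Dosage is the count of
#' alternate alleles; \code{./.} becomes \code{NA}.
#'
#' @param path path to a VCF (v4.x, plain text or gzip).
#' @param site_map either a data.frame with columns \code{id}, \code{site},
#'   or a path to a CSV/TSV file with those columns. Every VCF sample must
#'   appear.
#' @param min_call_rate loci called in a smaller fraction of individuals are
#'   dropped (guards degenerate inputs; upstream genotype filters are out of
#'   scope here).
#' @return a \code{genotype_matrix}.
#' @export
read_vcf <- function(path, site_map, min_call_rate = 0.5) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  is_snp <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_drop <- sum(!is_snp)
  if (n_drop > 0)
    message("read_vcf: dropped ", n_drop, " multiallelic/non-SNP record(s)")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[is_snp, , drop = FALSE]
  fix <- fix[is_snp, , drop = FALSE]
  if (nrow(fix) == 0L) stop("read_vcf: zero usable biallelic SNP records")

  if (is.character(site_map) && length(site_map) == 1L)
    site_map <- read_table_auto(site_map)
  site_map <- as.data.frame(site_map, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "site") %in% names(site_map)))
  samples <- colnames(gt)
  missing_samples <- setdiff(samples, site_map$id)
  if (length(missing_samples) > 0)
    stop(
      "read_vcf: sample(s) absent from site map: ",
      paste(missing_samples, collapse = ", ")
    )

  # GT strings -> dosage; tolerate phased separators
  clean <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt))
  code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  dos[] <- t(matrix(code[clean], nrow = nrow(gt)))

  loci <- data.frame(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
      paste0(fix$CHROM, ":", fix$POS), fix$ID
    ),
    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE
  )
  individuals <- data.frame(
    id = samples,
    site = site_map$site[match(samples, site_map$id)],
    stringsAsFactors = FALSE
  )
  g <- genotype_matrix(dos, loci, individuals)
  cr <- colMeans(!is.na(g$dosages))
  if (any(cr < min_call_rate)) {
    message(
      "read_vcf: dropped ", sum(cr < min_call_rate),
      " locus/loci with call rate < ", min_call_rate
    )
    g <- subset_genotypes(g, loci = cr >= min_call_rate)
  }
  if (n_loci(g) == 0L) stop("read_vcf: zero usable loci after call-rate guard")
  g
}

#' Write a genotype matrix as a VCF
#'
#' Emits a minimal VCF v4.2 with GT-only genotype columns, suitable for
#' round-tripping through \code{\link{read_vcf}}.
#'
#' @param g a \code{genotype_matrix}
#' @param path output file path (plain text).
#' @return \code{path}, invisibly.
#' @export
write_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=reefgen",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", g$individuals$id
    ), collapse = "\t")
  ), con)
  gt_code <- c("0/0", "0/1", "1/1")
  dos <- g$dosages
  gt <- matrix("./.", nrow = nrow(dos), ncol = ncol(dos))
  ok <- !is.na(dos)
  gt[ok] <- gt_code[dos[ok] + 1L]
  ref <- if (is.null(g$loci$ref)) rep("A", n_loci(g)) else g$loci$ref
  alt <- if (is.null(g$loci$alt)) rep("T", n_loci(g)) else g$loci$alt
  body <- paste(
    g$loci$chrom, g$loci$pos, g$loci$id, ref, alt, ".", "PASS", ".", "GT",
    apply(gt, 2, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(body, con)
  invisible(path)
}

#' Screen loci on global major-allele frequency
#'
#' Loci whose global major-allele frequency (computed on non-missing calls)
#' exceeds \code{max_major_freq} are removed; rare-variant loci bias outlier
#' scans and LD statistics.
#'
#' @param g a \code{genotype_matrix}
#' @param max_major_freq retain loci with major-allele frequency at or below
#'   this value; default 0.95.
#' @return a \code{genotype_matrix}, locus order preserved.
#' @export
screen_maf <- function(g, max_major_freq = 0.95) {
  stopifnot(max_major_freq >= 0.5, max_major_freq <= 1)
  p <- allele_freqs(g)$freq
  major <- pmax(p, 1 - p)
  keep <- !is.na(major) & major <= max_major_freq
  if (!any(keep)) stop("screen_maf: all loci removed")
  subset_genotypes(g, loci = keep)
}

#' Alternate-allele frequencies
#'
#' @param g a \code{genotype_matrix}
#' @param by_site if TRUE, return one frequency column per site; sites with
#'   zero calls at a locus report \code{NA}.
#' @return data.frame with \code{chrom}, \code{pos}, \code{id} and either a
#'   \code{freq} column or one column per site.
#' @export
allele_freqs <- function(g, by_site = FALSE) {
  out <- g$loci[, c("chrom", "pos", "id")]
  if (!by_site) {
    out$freq <- colMeans(g$dosages, na.rm = TRUE) / 2
    out$freq[colSums(!is.na(g$dosages)) == 0L] <- NA_real_
  } else {
    for (s in unique(sites_of(g))) {
      d <- g$dosages[sites_of(g) == s, , drop = FALSE]
      f <- colMeans(d, na.rm = TRUE) / 2
      f[colSums(!is.na(d)) == 0L] <- NA_real_
      out[[s]] <- f
    }
  }
  rownames(out) <- NULL
  out
}

# Read a delimited table, sniffing comma vs tab from the header line.
read_table_auto <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path,
    header = TRUE, sep = sep, stringsAsFactors = FALSE,
    check.names = FALSE
  )
}

#' Read per-site metadata
#'
#' Expected columns: \code{site}, \code{type} (natural/restored), \code{lat},
#' \code{lon}, and optionally \code{planting_seasons}, \code{broodstock_n},
#' \code{sex_ratio}, \code{reef_size}.
#'
#' @param path CSV/TSV file with a header.
#' @return data.frame.
#' @export
read_site_table <- function(path) {
  x <- read_table_auto(path)
  stopifnot(all(c("site", "type") %in% names(x)))
  if (anyDuplicated(x$site)) stop("duplicate site labels")
  if (is.null(x$planting_seasons)) x$planting_seasons <- 0L
  if (any(x$type == "natural" & x$planting_seasons > 0))
    stop("natural sites must have planting_seasons = 0")
  x
}

#' Read per-site environmental predictors
#'
#' One row per site; remaining columns are named environmental summaries
#' (e.g. mean_salinity, mean_wtemp, min_DO, mean_pH).
#'
#' @param path CSV/TSV file with a header; must contain a \code{site} column.
#' @return data.frame.
#' @export
read_env_table <- function(path) {
  x <- read_table_auto(path)
  stopifnot("site" %in% names(x))
  if (anyDuplicated(x$site)) stop("duplicate site labels in env table")
  x
}

#' Read a labeled square distance matrix
#'
#' @param path CSV with site labels as header and first column; values in km.
#' @return numeric matrix with dimnames; validated symmetric, zero diagonal.
#' @export
read_dist_matrix <- function(path) {
  x <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(x)
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    stop("distance matrix is not symmetric")
  if (any(diag(m) != 0)) stop("distance matrix diagonal must be zero")
  if (any(m < 0)) stop("distances must be nonnegative")
  m
}

#' Write a labeled square distance matrix
#' @param d numeric matrix with dimnames
#' @param path output CSV path
#' @return \code{path}, invisibly.
#' @export
write_dist_matrix <- function(d, path) {
  utils::write.csv(as.data.frame(d), path)
  invisible(path)
}
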