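SITE_STAT_COLS <- c("QD", "FS", "MQ", "ReadPosRankSum", "MQRankSum", "SOR")
IMPACT_CLASSES <- c("high", "moderate", "low", "modifier")

#' Construct a variant table
#'
#' A variant table is a plain `data.frame`, one row per site, ordered strictly
#' by (chrom, pos), carrying per-site metadata: position (1-based, VCF
#' convention), alleles, minor allele frequency, functional impact class,
#' array-panel membership flag and GATK-style site filter statistics
#' (QD, FS, MQ, ReadPosRankSum, MQRankSum, SOR).
#'
#' @param chrom chromosome labels (character).
#' @param pos 1-based positions, unique within chromosome.
#' @param ref_allele,alt_allele single-nucleotide alleles.
#' @param maf minor allele frequencies in \[0, 0.5\] (NA allowed until computed).
#' @param impact_class one of `"high"`, `"moderate"`, `"low"`, `"modifier"`
#'   (NA allowed until assigned).
#' @param on_array logical flag: site is on the SNP-array panel.
#' @param site_stats optional data.frame with columns among
#'   `QD, FS, MQ, ReadPosRankSum, MQRankSum, SOR`.
#' @return a `data.frame` of class `variant_table`.
#' @export
variant_table <- function(chrom, pos, ref_allele = "A", alt_allele = "C",
                          maf = NA_real_, impact_class = NA_character_,
                          on_array = FALSE, site_stats = NULL) {
  n <- length(pos)
  vt <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref_allele = rep_len(ref_allele, n),
                   alt_allele = rep_len(alt_allele, n),
                   maf = rep_len(as.numeric(maf), n),
                   impact_class = rep_len(as.character(impact_class), n),
                   on_array = rep_len(as.logical(on_array), n),
                   stringsAsFactors = FALSE)
  for (s in SITE_STAT_COLS) {
    vt[[s]] <- if (!is.null(site_stats) && s %in% names(site_stats))
      as.numeric(site_stats[[s]]) else NA_real_
  }
  class(vt) <- c("variant_table", "data.frame")
  validate_variant_table(vt)
  vt
}

validate_variant_table <- function(vt) {
  stopifnot(is.data.frame(vt))
  if (any(!is.na(vt$maf) & (vt$maf < 0 | vt$maf > 0.5)))
    stop("variant_table: maf must lie in [0, 0.5]", call. = FALSE)
  key <- paste(vt$chrom, vt$pos)
  if (anyDuplicated(key)) stop("variant_table: pos must be unique within chrom", call. = FALSE)
  ord <- order(vt$chrom, vt$pos)
  if (!identical(ord, seq_len(nrow(vt))))
    stop("variant_table: sites must be sorted by (chrom, pos)", call. = FALSE)
  bad <- !is.na(vt$impact_class) & !(vt$impact_class %in% IMPACT_CLASSES)
  if (any(bad)) stop("variant_table: unknown impact_class", call. = FALSE)
  invisible(vt)
}

#' Construct a phased haplotype panel
#'
#' Holds phased 0/1 alleles for diploid samples over the ordered sites of a
#' [variant_table()]: row `2i - 1` and `2i` of `haplotypes` are the two
#' haplotypes of sample `i`. This is both the truth substrate of the
#' simulator and the reference panel consumed by the imputation engines.
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param haplotypes integer matrix (2 * n_samples) x n_sites with values 0/1.
#' @param sites a [variant_table()] with one row per haplotype column.
#' @param phased logical; truth and reference panels are phased.
#' @param pedigree optional data.frame (sample, sire, dam) for bred panels.
#' @return an object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(sample_ids, haplotypes, sites, phased = TRUE,
                            pedigree = NULL) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (nrow(haplotypes) != 2L * length(sample_ids))
    stop("haplotype_panel: need exactly two haplotypes per sample", call. = FALSE)
  if (ncol(haplotypes) != nrow(sites))
    stop("haplotype_panel: haplotype columns must match sites rows", call. = FALSE)
  if (anyNA(haplotypes) || !all(haplotypes %in% c(0L, 1L)))
    stop("haplotype_panel: alleles must be 0/1", call. = FALSE)
  if (anyDuplicated(sample_ids)) stop("haplotype_panel: duplicated sample ids", call. = FALSE)
  validate_variant_table(sites)
  structure(list(sample_ids = as.character(sample_ids), haplotypes = haplotypes,
                 sites = sites, phased = isTRUE(phased), pedigree = pedigree),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %d samples x %d sites (%s), %s\n",
              length(x$sample_ids), ncol(x$haplotypes),
              paste(unique(x$sites$chrom), collapse = ","),
              if (x$phased) "phased" else "unphased"))
  invisible(x)
}

n_samples <- function(x) length(x$sample_ids)

hap_rows <- function(sample_index) {
  as.vector(rbind(2L * sample_index - 1L, 2L * sample_index))
}

#' Diploid genotypes implied by a haplotype panel
#'
#' @param panel a [haplotype_panel()].
#' @return integer matrix n_samples x n_sites of allele counts in \{0, 1, 2\},
#'   with sample ids as rownames.
#' @export
panel_genotypes <- function(panel) {
  n <- n_samples(panel)
  g <- panel$haplotypes[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    panel$haplotypes[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  rownames(g) <- panel$sample_ids
  g
}

#' Restrict a haplotype panel to a sample subset and/or site subset
#'
#' @param panel a [haplotype_panel()].
#' @param samples character vector of sample ids to keep (default all).
#' @param site_idx integer vector of site indices to keep (default all).
#' @return a [haplotype_panel()].
#' @export
subset_panel <- function(panel, samples = panel$sample_ids,
                         site_idx = seq_len(nrow(panel$sites))) {
  si <- match(samples, panel$sample_ids)
  if (anyNA(si)) stop("subset_panel: unknown sample id", call. = FALSE)
  sites <- panel$sites[site_idx, , drop = FALSE]
  rownames(sites) <- NULL
  haplotype_panel(samples,
                  panel$haplotypes[hap_rows(si), site_idx, drop = FALSE],
                  sites, phased = panel$phased)
}

#' Construct a genotype matrix
#'
#' Per-sample, per-site genotype codes \{0, 1, 2, NA\} plus optional
#' per-genotype phred-scaled quality scores and continuous dosages.
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param geno integer matrix n_samples x n_sites; NA encodes missing.
#' @param sites a [variant_table()].
#' @param gq optional integer matrix of genotype quality scores.
#' @param dosage optional numeric matrix of alt-allele dosages in \[0, 2\].
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sample_ids, geno, sites, gq = NULL, dosage = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != length(sample_ids))
    stop("genotype_matrix: one row per sample required", call. = FALSE)
  if (ncol(geno) != nrow(sites))
    stop("genotype_matrix: geno columns must match sites rows", call. = FALSE)
  if (!all(geno %in% c(0L, 1L, 2L) | is.na(geno)))
    stop("genotype_matrix: genotype codes must be 0/1/2/NA", call. = FALSE)
  validate_variant_table(sites)
  rownames(geno) <- sample_ids
  structure(list(sample_ids = as.character(sample_ids), geno = geno,
                 sites = sites, gq = gq, dosage = dosage),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d sites, %.2f%% missing\n",
              nrow(x$geno), ncol(x$geno), 100 * mean(is.na(x$geno))))
  invisible(x)
}

#' Observed alternate-allele frequency per site
#'
#' Computed from non-missing genotypes: alt allele count over 2 x (number of
#' non-missing samples). Sites with no calls return NA.
#'
#' @param gm a [genotype_matrix()].
#' @return numeric vector of alt-allele frequencies.
#' @export
alt_freq <- function(gm) {
  nn <- colSums(!is.na(gm$geno))
  ac <- colSums(gm$geno, na.rm = TRUE)
  ifelse(nn > 0, ac / (2 * nn), NA_real_)
}

#' Minor allele frequency per site of a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @return numeric vector in \[0, 0.5\].
#' @export
compute_maf <- function(gm) {
  p <- alt_freq(gm)
  pmin(p, 1 - p)
}

#' Construct an imputation result
#'
#' @param sample_ids target sample identifiers.
#' @param dosage numeric matrix n_samples x n_sites of alt-allele dosages in
#'   \[0, 2\].
#' @param best_guess integer matrix of hard-called genotypes.
#' @param rsq numeric vector: per-site model-based imputation quality in
#'   \[0, 1\] (estimated squared correlation with the unobserved truth).
#' @param sites a [variant_table()].
#' @param engine label of the producing engine ("lshmm", "osw", "import").
#' @return an object of class `imputation_result`.
#' @export
imputation_result <- function(sample_ids, dosage, best_guess, rsq, sites,
                              engine) {
  dosage <- as.matrix(dosage)
  if (any(dosage < -1e-9 | dosage > 2 + 1e-9, na.rm = TRUE))
    stop("imputation_result: dosages must lie in [0, 2]", call. = FALSE)
  if (length(rsq) != nrow(sites))
    stop("imputation_result: rsq must be defined for every site", call. = FALSE)
  rownames(dosage) <- sample_ids
  rownames(best_guess) <- sample_ids
  structure(list(sample_ids = as.character(sample_ids), dosage = dosage,
                 best_guess = best_guess, rsq = pmin(pmax(rsq, 0), 1),
                 sites = sites, engine = engine),
            class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("<imputation_result> engine=%s, %d samples x %d sites\n",
              x$engine, nrow(x$dosage), ncol(x$dosage)))
  invisible(x)
}

# Hard-call dosages; exact .5 halves round toward the panel's major genotype
# (up when the alt allele is the major allele at that site, down otherwise).
hard_call <- function(dosage, alt_is_major) {
  lower <- floor(dosage)
  frac <- dosage - lower
  up <- frac > 0.5 | (abs(frac - 0.5) < 1e-12 &
                        rep(alt_is_major, each = nrow(dosage)))
  bg <- lower + as.integer(up)
  storage.mode(bg) <- "integer"
  pmin(pmax(bg, 0L), 2L)
}

# Minimac-style model Rsq from dosages alone: empirical (population) variance
# of half-dosages over the binomial variance p(1-p); 0 at monomorphic sites.
rsq_from_dosage <- function(dosage) {
  p <- colMeans(dosage) / 2
  v <- apply(dosage / 2, 2, pop_var)
  rsq <- ifelse(p <= 0 | p >= 1, 0, v / (p * (1 - p)))
  pmin(pmax(rsq, 0), 1)
}
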