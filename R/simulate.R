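#' Simulation configuration
#'
#' Bundles every knob of the synthetic-population generator. Defaults
#' describe the study conditions the evaluation harness targets: a diploid
#' population bred from a founder pool, a site frequency spectrum skewed
#' toward rare variants (about 13.5% of segregating sites at MAF <= 0.03),
#' linkage disequilibrium induced by ancestral-mosaic haplotype copying, a
#' sparse MAF-ascertained array panel (~1.9% of sequence sites), and
#' sequencing-style genotype artifacts (genotype errors, phred-scaled GQ
#' scores, GATK-style site statistics with a configurable failure fraction).
#'
#' @param n_founders number of founder animals.
#' @param n_samples number of bred study animals.
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_bp chromosome length in base pairs.
#' @param n_sites_per_chrom variant sites per chromosome (>= 2).
#' @param array_fraction fraction of sites on the array panel, in (0, 1).
#' @param sfs_shape shape parameter of the symmetric Beta law for ancestral
#'   allele frequencies; smaller values skew the folded spectrum rarer.
#' @param n_ancestral number of ancestral haplotypes in the mosaic model.
#' @param recent_variant_fraction fraction of sites carrying a recent
#'   single-origin mutation instead of an ancestral allele: such sites are
#'   monomorphic in the ancestral pool and the derived allele is placed on
#'   exactly one founder haplotype, so carriers share one long recent
#'   haplotype but the allele is weakly tagged by older background LD --
#'   the structure that makes rare variants hard to impute.
#' @param founder_usage_shape gamma shape of the parent-usage weights in
#'   breeding; small values give the heavy-tailed popular-sire usage typical
#'   of cattle populations (a few sires leave many offspring).
#' @param n_generations number of non-overlapping generations bred from the
#'   founder pool; successive meioses shorten the identical-by-descent
#'   segments carrying recent mutations, as in a real pedigree.
#' @param recomb_rate recombination rate in Morgans per bp (default 1 cM/Mb).
#' @param mosaic_switch_rate per-site probability that a founder haplotype
#'   switches its ancestral template.
#' @param genotype_error_rate fraction of sequenced genotypes replaced by a
#'   random incorrect code.
#' @param gq_distribution_params c(mean, sd) of the Gaussian from which
#'   phred-scaled genotype qualities are drawn (clipped to \[0, 99\]).
#' @param annotation_proportions named fractions over the impact classes
#'   high/moderate/low/modifier; must sum to 1.
#' @param rare_enrichment_high_moderate target share of MAF <= 0.03 variants
#'   inside the high+moderate classes.
#' @param site_stat_fail named fractions of sites constructed to violate each
#'   site-statistic QC threshold.
#' @param seed integer seed; a fixed seed makes every product byte-identical.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 100L, n_samples = 200L,
                       n_chromosomes = 2L, chrom_length_bp = 1e8,
                       n_sites_per_chrom = 10000L, array_fraction = 0.0186,
                       sfs_shape = 0.35, n_ancestral = 80L,
                       recent_variant_fraction = 0.40,
                       founder_usage_shape = 0.25, n_generations = 4L,
                       recomb_rate = 1e-8, mosaic_switch_rate = 0.01,
                       genotype_error_rate = 0.004,
                       gq_distribution_params = c(mean = 45, sd = 15),
                       annotation_proportions = c(high = 0.01, moderate = 0.03,
                                                  low = 0.06, modifier = 0.90),
                       rare_enrichment_high_moderate = 0.15,
                       site_stat_fail = c(QD = 0.005, FS = 0.005, MQ = 0.005,
                                          ReadPosRankSum = 0.005,
                                          MQRankSum = 0.005, SOR = 0.005),
                       seed = 1L) {
  cfg <- list(n_founders = n_founders, n_samples = n_samples,
              n_chromosomes = n_chromosomes, chrom_length_bp = chrom_length_bp,
              n_sites_per_chrom = n_sites_per_chrom,
              array_fraction = array_fraction, sfs_shape = sfs_shape,
              n_ancestral = n_ancestral,
              recent_variant_fraction = recent_variant_fraction,
              founder_usage_shape = founder_usage_shape,
              n_generations = n_generations,
              recomb_rate = recomb_rate,
              mosaic_switch_rate = mosaic_switch_rate,
              genotype_error_rate = genotype_error_rate,
              gq_distribution_params = gq_distribution_params,
              annotation_proportions = annotation_proportions,
              rare_enrichment_high_moderate = rare_enrichment_high_moderate,
              site_stat_fail = site_stat_fail, seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (!is_count(cfg$n_founders, 1)) stop_field("n_founders", "positive count required")
  if (!is_count(cfg$n_samples, 1)) stop_field("n_samples", "positive count required")
  if (!is_count(cfg$n_chromosomes, 1)) stop_field("n_chromosomes", "positive count required")
  if (!is_count(cfg$chrom_length_bp, 1)) stop_field("chrom_length_bp", "positive integer bp required")
  if (!is_count(cfg$n_sites_per_chrom, 2)) stop_field("n_sites_per_chrom", "must be >= 2")
  if (!is_fraction(cfg$array_fraction, 0, 1, open_lo = TRUE, open_hi = TRUE))
    stop_field("array_fraction", "must lie in (0, 1)")
  if (!(is.numeric(cfg$sfs_shape) && cfg$sfs_shape > 0))
    stop_field("sfs_shape", "positive real required")
  if (!is_count(cfg$n_ancestral, 2)) stop_field("n_ancestral", "at least 2 ancestral haplotypes")
  if (!is_fraction(cfg$recent_variant_fraction, 0, 1, open_hi = TRUE))
    stop_field("recent_variant_fraction", "must lie in [0, 1)")
  if (!(is.numeric(cfg$founder_usage_shape) && cfg$founder_usage_shape > 0))
    stop_field("founder_usage_shape", "positive real required")
  if (!is_count(cfg$n_generations, 1)) stop_field("n_generations", "positive count required")
  if (!(is.numeric(cfg$recomb_rate) && cfg$recomb_rate >= 0))
    stop_field("recomb_rate", "non-negative Morgans/bp required")
  if (!is_fraction(cfg$mosaic_switch_rate)) stop_field("mosaic_switch_rate", "must lie in [0, 1]")
  if (!is_fraction(cfg$genotype_error_rate)) stop_field("genotype_error_rate", "must lie in [0, 1]")
  g <- cfg$gq_distribution_params
  if (!(is.numeric(g) && length(g) == 2L && g[2] >= 0))
    stop_field("gq_distribution_params", "c(mean, sd) with sd >= 0 required")
  ap <- cfg$annotation_proportions
  if (is.null(names(ap)) || !all(names(ap) %in% IMPACT_CLASSES))
    stop_field("annotation_proportions", "names must be impact classes")
  if (any(ap < 0) || abs(sum(ap) - 1) > 1e-8)
    stop_field("annotation_proportions", "must be non-negative and sum to 1")
  if (!is_fraction(cfg$rare_enrichment_high_moderate))
    stop_field("rare_enrichment_high_moderate", "must lie in [0, 1]")
  if (any(cfg$site_stat_fail < 0 | cfg$site_stat_fail > 1))
    stop_field("site_stat_fail", "fractions in [0, 1] required")
  if (!is_count(cfg$seed, 0)) stop_field("seed", "non-negative integer required")
  cfg
}

nucleotide_pair <- function(n) {
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
  list(ref = ref, alt = unname(alt))
}

#' Simulate a founder haplotype panel
#'
#' Per-site allele frequencies are drawn from a symmetric Beta(sfs_shape,
#' sfs_shape) law and realized in a pool of ancestral haplotypes; each founder
#' haplotype is then an ancestral mosaic, copying one ancestor and switching
#' templates with probability `mosaic_switch_rate` at each successive site.
#' The mosaic induces linkage disequilibrium that decays with distance, which
#' is the haplotype sharing both imputation engines exploit. A fraction
#' `recent_variant_fraction` of sites instead carry a recent single-origin
#' mutation: monomorphic in the ancestral pool, the derived allele is placed
#' on exactly one founder haplotype, so its carriers descend from one long
#' recent haplotype rather than from the older mosaic background.
#'
#' @param config a [sim_config()].
#' @return a phased [haplotype_panel()] of `n_founders` samples, with realized
#'   minor allele frequencies filled in.
#' @export
simulate_founders <- function(config) {
  config <- validate_sim_config(config)
  local_seed(config$seed)
  n_hap <- 2L * config$n_founders
  m_c <- config$n_sites_per_chrom
  K <- config$n_ancestral
  chrom_sites <- vector("list", config$n_chromosomes)
  chrom_haps <- vector("list", config$n_chromosomes)
  for (cc in seq_len(config$n_chromosomes)) {
    pos <- sort(sample.int(config$chrom_length_bp, m_c))
    p <- rbeta(m_c, config$sfs_shape, config$sfs_shape)
    recent <- which(runif(m_c) < config$recent_variant_fraction)
    p[recent] <- 0  # monomorphic in the ancestral pool
    anc <- matrix(rbinom(K * m_c, 1L, rep(p, each = K)), nrow = K)
    H <- matrix(0L, nrow = n_hap, ncol = m_c)
    for (h in seq_len(n_hap)) {
      seg <- cumsum(c(TRUE, runif(m_c - 1L) < config$mosaic_switch_rate))
      anc_of_seg <- sample.int(K, max(seg), replace = TRUE)
      H[h, ] <- anc[cbind(anc_of_seg[seg], seq_len(m_c))]
    }
    if (length(recent))  # one origin: the derived allele rides one haplotype
      H[cbind(sample.int(n_hap, length(recent), replace = TRUE), recent)] <- 1L
    al <- nucleotide_pair(m_c)
    chrom_sites[[cc]] <- variant_table(chrom = sprintf("chr%d", cc), pos = pos,
                                       ref_allele = al$ref, alt_allele = al$alt)
    chrom_haps[[cc]] <- H
  }
  sites <- do.call(rbind, chrom_sites)
  class(sites) <- c("variant_table", "data.frame")
  panel <- haplotype_panel(sprintf("F%03d", seq_len(config$n_founders)),
                           do.call(cbind, chrom_haps), sites)
  refresh_panel_maf(panel)
}

# Realized MAF: allele count over 2 * n_samples, exactly.
refresh_panel_maf <- function(panel) {
  p <- colMeans(panel$haplotypes)
  panel$sites$maf <- pmin(p, 1 - p)
  panel
}

#' Breed a study population from founders
#'
#' Each offspring draws two distinct parents from the previous generation
#' with heavy-tailed usage weights (gamma with shape `founder_usage_shape`,
#' emulating popular-sire breeding); each transmitted gamete recombines the
#' parent's haplotype pair with a Poisson(recomb_rate x chrom_length_bp)
#' crossover count per chromosome and uniform crossover positions. This is
#' repeated for `n_generations` non-overlapping generations of `n_samples`
#' individuals. Truth haplotypes, the final-generation pedigree and the
#' parent generation panel (for Mendelian checks) are retained.
#'
#' @param founders a phased [haplotype_panel()] with at least 2 samples.
#' @param config a [sim_config()]; each generation re-seeds the generator
#'   from an offset of `config$seed`, so founder and breeding draws are
#'   decoupled stages of the same seed stream.
#' @return a phased [haplotype_panel()] of the final generation, with a
#'   `pedigree` data.frame and the parent generation in `$parents`.
#' @export
breed_population <- function(founders, config) {
  config <- validate_sim_config(config)
  if (!founders$phased) stop("breed_population: founders must be phased", call. = FALSE)
  if (n_samples(founders) < 2L)
    stop("breed_population: fewer than 2 founders", call. = FALSE)
  gen <- founders
  for (g in seq_len(config$n_generations)) {
    parents <- gen
    prefix <- if (g == config$n_generations) "S" else sprintf("G%d_", g)
    gen <- breed_generation(parents, config, seed = config$seed + 11L * g,
                            prefix = prefix)
    gen$parents <- if (g == config$n_generations) parents else NULL
  }
  gen
}

breed_generation <- function(parents, config, seed, prefix) {
  local_seed(seed)
  sites <- parents$sites
  chroms <- unique(sites$chrom)
  n_off <- config$n_samples
  H <- matrix(0L, nrow = 2L * n_off, ncol = nrow(sites))
  ped <- data.frame(sample = sprintf("%s%04d", prefix, seq_len(n_off)),
                    sire = NA_character_, dam = NA_character_)
  usage <- pmax(rgamma(n_samples(parents), shape = config$founder_usage_shape),
                1e-12)
  for (i in seq_len(n_off)) {
    par_idx <- sample.int(n_samples(parents), 2L, prob = usage)
    ped$sire[i] <- parents$sample_ids[par_idx[1]]
    ped$dam[i] <- parents$sample_ids[par_idx[2]]
    for (k in 1:2) {
      prow <- 2L * par_idx[k] - 1L
      for (cc in chroms) {
        idx <- which(sites$chrom == cc)
        pos <- sites$pos[idx]
        n_xo <- rpois(1L, config$recomb_rate * config$chrom_length_bp)
        xo <- sort(runif(n_xo, 1, config$chrom_length_bp))
        use_second <- (findInterval(pos, xo) + sample.int(2L, 1L)) %% 2L
        src <- ifelse(use_second == 1L,
                      parents$haplotypes[prow + 1L, idx],
                      parents$haplotypes[prow, idx])
        H[2L * i - 2L + k, idx] <- src
      }
    }
  }
  panel <- haplotype_panel(ped$sample, H, sites, pedigree = ped)
  refresh_panel_maf(panel)
}

# Largest-remainder apportionment of n among proportions p (sums exactly n).
apportion <- function(n, p) {
  raw <- n * p / sum(p)
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Assign functional-impact classes to sites
#'
#' Draws impact labels with the configured marginal proportions while tilting
#' the within-class composition so that the share of rare variants
#' (MAF <= 0.03) inside the high+moderate classes matches
#' `rare_enrichment_high_moderate`, emulating the enrichment of low-frequency
#' alleles among protein-affecting variants.
#'
#' @param sites a [variant_table()] with `maf` computed.
#' @param config a [sim_config()].
#' @param seed integer seed for the label draw.
#' @return the [variant_table()] with `impact_class` filled.
#' @export
assign_annotations <- function(sites, config, seed = config$seed) {
  config <- validate_sim_config(config)
  if (anyNA(sites$maf)) stop("assign_annotations: maf must be computed first", call. = FALSE)
  local_seed(seed)
  n <- nrow(sites)
  ap <- config$annotation_proportions[IMPACT_CLASSES]
  ap[is.na(ap)] <- 0
  names(ap) <- IMPACT_CLASSES
  counts <- stats::setNames(apportion(n, ap), IMPACT_CLASSES)
  rare <- which(sites$maf <= 0.03)
  common <- setdiff(seq_len(n), rare)
  n_hm <- counts[["high"]] + counts[["moderate"]]
  want_rare_hm <- min(round(config$rare_enrichment_high_moderate * n_hm), length(rare))
  hm_rare <- if (want_rare_hm > 0) sample(rare, want_rare_hm) else integer(0)
  n_common_hm <- n_hm - length(hm_rare)
  if (n_common_hm <= length(common)) {
    hm_common <- if (n_common_hm > 0)
      common[sample.int(length(common), n_common_hm)] else integer(0)
  } else {  # spill into the unused rare pool only when common sites run out
    spill <- setdiff(rare, hm_rare)
    hm_common <- c(common,
                   spill[sample.int(length(spill), n_common_hm - length(common))])
  }
  hm <- sample(c(hm_rare, hm_common))
  labels <- rep(NA_character_, n)
  if (counts[["high"]] > 0) labels[hm[seq_len(counts[["high"]])]] <- "high"
  if (counts[["moderate"]] > 0)
    labels[hm[counts[["high"]] + seq_len(counts[["moderate"]])]] <- "moderate"
  rest <- sample(which(is.na(labels)))
  if (counts[["low"]] > 0) labels[rest[seq_len(counts[["low"]])]] <- "low"
  labels[is.na(labels)] <- "modifier"
  sites$impact_class <- labels
  sites
}

#' Degrade truth haplotypes into sequencing-style called genotypes
#'
#' Genotypes are the haplotype allele sums, with a fraction
#' `genotype_error_rate` replaced by one of the two incorrect codes; every
#' genotype receives a phred-scaled GQ drawn from the configured Gaussian
#' (clipped to \[0, 99\]); every site receives GATK-style filter statistics
#' drawn so that the configured fraction of sites violates each QC threshold.
#'
#' @param panel a phased truth [haplotype_panel()].
#' @param config a [sim_config()]; the generator is seeded with `seed + 2`.
#' @return a [genotype_matrix()] with `gq` and populated site statistics.
#' @export
degrade_to_sequenced_genotypes <- function(panel, config) {
  config <- validate_sim_config(config)
  if (!panel$phased) stop("degrade_to_sequenced_genotypes: panel must be phased", call. = FALSE)
  local_seed(config$seed + 2L)
  g <- panel_genotypes(panel)
  n <- length(g)
  err <- which(runif(n) < config$genotype_error_rate)
  if (length(err)) {
    shift <- sample.int(2L, length(err), replace = TRUE)
    g[err] <- (g[err] + shift) %% 3L
  }
  gq <- matrix(pmin(pmax(round(rnorm(n, config$gq_distribution_params[1],
                                     config$gq_distribution_params[2])), 0), 99),
               nrow = nrow(g))
  storage.mode(gq) <- "integer"
  m <- nrow(panel$sites)
  draw_stat <- function(frac, pass_lo, pass_hi, fail_lo, fail_hi) {
    fail <- runif(m) < frac
    ifelse(fail, runif(m, fail_lo, fail_hi), runif(m, pass_lo, pass_hi))
  }
  f <- config$site_stat_fail
  sites <- panel$sites
  sites$QD <- draw_stat(f[["QD"]], 2, 35, 0, 2)
  sites$FS <- draw_stat(f[["FS"]], 0, 60, 60.0001, 200)
  sites$MQ <- draw_stat(f[["MQ"]], 40, 60, 20, 40)
  sites$ReadPosRankSum <- draw_stat(f[["ReadPosRankSum"]], -8, 8, -20, -8.0001)
  sites$MQRankSum <- draw_stat(f[["MQRankSum"]], -12.5, 12.5, -25, -12.5001)
  sites$SOR <- draw_stat(f[["SOR"]], 0, 3, 3.0001, 9)
  genotype_matrix(panel$sample_ids, g, sites, gq = gq)
}

#' Flag array-panel sites
#'
#' Samples approximately `array_fraction` of sites per chromosome with
#' probability proportional to MAF, mimicking the common-variant ascertainment
#' of commercial high-density chips.
#'
#' @param sites a [variant_table()] with `maf` computed.
#' @param array_fraction fraction of sites to flag, in (0, 1).
#' @param seed integer seed.
#' @return the [variant_table()] with `on_array` set.
#' @export
select_array_sites <- function(sites, array_fraction, seed) {
  if (!is_fraction(array_fraction, 0, 1, open_lo = TRUE, open_hi = TRUE))
    stop_field("array_fraction", "must lie in (0, 1)")
  local_seed(seed)
  sites$on_array <- FALSE
  for (cc in unique(sites$chrom)) {
    idx <- which(sites$chrom == cc)
    n_arr <- round(array_fraction * length(idx))
    if (n_arr < 2L)
      stop(sprintf("select_array_sites: array_fraction yields %d (< 2) array sites on %s",
                   n_arr, cc), call. = FALSE)
    w <- pmax(sites$maf[idx], 1e-9)
    chosen <- idx[sample.int(length(idx), n_arr, prob = w)]
    sites$on_array[chosen] <- TRUE
  }
  sites
}

#' Fraction of rare segregating sites
#'
#' Share of sites at `min_maf <= MAF <= thresh` among sites with
#' `MAF >= min_maf`; the default conditioning mirrors a spectrum already
#' filtered at MAF < 0.01.
#'
#' @param maf numeric vector of minor allele frequencies.
#' @param thresh rare-variant threshold (default 0.03).
#' @param min_maf segregating-site floor (default 0.01).
#' @return a fraction in \[0, 1\].
#' @export
rare_fraction <- function(maf, thresh = 0.03, min_maf = 0.01) {
  keep <- maf >= min_maf
  if (!any(keep)) return(NA_real_)
  mean(maf[keep] <= thresh)
}
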