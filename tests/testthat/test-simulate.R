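small_cfg <- function(...) {
  defaults <- list(n_founders = 20L, n_samples = 30L, n_chromosomes = 2L,
                   chrom_length_bp = 2e7, n_sites_per_chrom = 300L,
                   array_fraction = 0.1, seed = 3L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("invalid configuration is rejected naming the offending field", {
  expect_error(sim_config(array_fraction = 1), "array_fraction")
  expect_error(sim_config(n_sites_per_chrom = 1), "n_sites_per_chrom")
  expect_error(sim_config(sfs_shape = -1), "sfs_shape")
  expect_error(sim_config(annotation_proportions = c(high = 0.5, modifier = 0.4)),
               "annotation_proportions")
  expect_error(sim_config(mosaic_switch_rate = 2), "mosaic_switch_rate")
  expect_error(sim_config(gq_distribution_params = 1), "gq_distribution_params")
})

test_that("a fixed seed reproduces every simulation product byte-identically", {
  cfg <- small_cfg()
  f1 <- simulate_founders(cfg); f2 <- simulate_founders(cfg)
  expect_identical(f1$haplotypes, f2$haplotypes)
  expect_identical(f1$sites, f2$sites)
  p1 <- breed_population(f1, cfg); p2 <- breed_population(f2, cfg)
  expect_identical(p1$haplotypes, p2$haplotypes)
  g1 <- degrade_to_sequenced_genotypes(p1, cfg)
  g2 <- degrade_to_sequenced_genotypes(p2, cfg)
  expect_identical(g1$geno, g2$geno)
  expect_identical(g1$gq, g2$gq)
  s1 <- select_array_sites(p1$sites, 0.1, seed = 9)
  s2 <- select_array_sites(p2$sites, 0.1, seed = 9)
  expect_identical(s1$on_array, s2$on_array)
})

test_that("without template switching founders collapse onto the ancestral pool", {
  cfg <- small_cfg(n_ancestral = 2L, mosaic_switch_rate = 0,
                   recent_variant_fraction = 0)
  f <- simulate_founders(cfg)
  for (cc in unique(f$sites$chrom)) {
    H <- f$haplotypes[, f$sites$chrom == cc, drop = FALSE]
    expect_lte(nrow(unique(H)), 2L)
  }
})

test_that("realized MAF equals the allele count over 2n exactly", {
  cfg <- small_cfg()
  pop <- breed_population(simulate_founders(cfg), cfg)
  ac <- colSums(pop$haplotypes)
  expect_equal(pop$sites$maf,
               pmin(ac, 2 * length(pop$sample_ids) - ac) /
                 (2 * length(pop$sample_ids)))
})

test_that("every child haplotype is Mendelian-consistent with its stored parents", {
  cfg <- small_cfg()
  pop <- breed_population(simulate_founders(cfg), cfg)
  expect_false(is.null(pop$parents))
  for (i in seq_along(pop$sample_ids)) {
    for (k in 1:2) {
      par_id <- if (k == 1) pop$pedigree$sire[i] else pop$pedigree$dam[i]
      pi <- match(par_id, pop$parents$sample_ids)
      child <- pop$haplotypes[2L * i - 2L + k, ]
      p1 <- pop$parents$haplotypes[2L * pi - 1L, ]
      p2 <- pop$parents$haplotypes[2L * pi, ]
      expect_true(all(child == p1 | child == p2))
    }
  }
})

test_that("without recombination each gamete is an intact parental haplotype", {
  cfg <- small_cfg(recomb_rate = 0, n_generations = 1L)
  pop <- breed_population(simulate_founders(cfg), cfg)
  for (i in seq_len(5)) {
    pi <- match(pop$pedigree$sire[i], pop$parents$sample_ids)
    for (cc in unique(pop$sites$chrom)) {
      idx <- pop$sites$chrom == cc
      child <- pop$haplotypes[2L * i - 1L, idx]
      expect_true(identical(child, pop$parents$haplotypes[2L * pi - 1L, idx]) ||
                    identical(child, pop$parents$haplotypes[2L * pi, idx]))
    }
  }
})

test_that("crossover counts match the Poisson expectation on a 1-Morgan chromosome", {
  # founders carry all-0 / all-1 haplotype pairs, so every gamete switch is
  # a visible crossover; the Monte-Carlo mean must approach 1 per Morgan
  m <- 400L
  sites <- variant_table("chr1", pos = seq(2.5e5, 1e8, length.out = m))
  H <- matrix(rep(c(0L, 1L), each = 1, times = 1), nrow = 4, ncol = m)
  H[c(1, 3), ] <- 0L; H[c(2, 4), ] <- 1L
  founders <- haplotype_panel(c("A", "B"), H, sites)
  cfg <- sim_config(n_founders = 2L, n_samples = 300L, n_chromosomes = 1L,
                    chrom_length_bp = 1e8, n_sites_per_chrom = m,
                    recomb_rate = 1e-8, n_generations = 1L, seed = 21L)
  pop <- breed_population(founders, cfg)
  switches <- apply(pop$haplotypes, 1, function(h) sum(diff(h) != 0))
  expect_gt(mean(switches), 0.85)
  expect_lt(mean(switches), 1.15)
})

test_that("sequencing degradation injects errors and artifacts at the configured rates", {
  cfg <- small_cfg(n_sites_per_chrom = 1500L, genotype_error_rate = 0.01,
                   site_stat_fail = c(QD = 0.02, FS = 0.005, MQ = 0.005,
                                      ReadPosRankSum = 0.005, MQRankSum = 0.005,
                                      SOR = 0.005))
  pop <- breed_population(simulate_founders(cfg), cfg)
  gm <- degrade_to_sequenced_genotypes(pop, cfg)
  truth <- panel_genotypes(pop)
  n <- length(truth)
  mis <- mean(gm$geno != truth)
  expect_lt(abs(mis - 0.01), 3 * sqrt(0.01 * 0.99 / n))
  frac_qd <- mean(gm$sites$QD < 2.0)
  expect_lt(abs(frac_qd - 0.02),
            3 * sqrt(0.02 * 0.98 / nrow(gm$sites)) + 1e-9)
  # error-free limit reproduces truth exactly
  cfg0 <- small_cfg(genotype_error_rate = 0)
  pop0 <- breed_population(simulate_founders(cfg0), cfg0)
  gm0 <- degrade_to_sequenced_genotypes(pop0, cfg0)
  expect_identical(unname(gm0$geno), unname(panel_genotypes(pop0)))
})

test_that("annotation labels honour marginal proportions and rare enrichment", {
  cfg <- small_cfg()
  pop <- breed_population(simulate_founders(cfg), cfg)
  all_mod <- assign_annotations(pop$sites,
                                small_cfg(annotation_proportions = c(modifier = 1)),
                                seed = 1)
  expect_true(all(all_mod$impact_class == "modifier"))
  props <- c(high = 0.1, moderate = 0.2, low = 0.3, modifier = 0.4)
  ann <- assign_annotations(pop$sites, small_cfg(annotation_proportions = props),
                            seed = 2)
  tab <- table(factor(ann$impact_class, levels = names(props)))
  expect_true(all(abs(tab / nrow(ann) - props) < 2 / nrow(ann)))
  # two seeds: different labels, identical marginals
  ann2 <- assign_annotations(pop$sites, small_cfg(annotation_proportions = props),
                             seed = 3)
  expect_false(identical(ann$impact_class, ann2$impact_class))
  expect_identical(table(ann$impact_class), table(ann2$impact_class))
})

test_that("rare-variant share inside high+moderate tracks the enrichment target", {
  shares <- sapply(1:3, function(s) {
    cfg <- sim_config(n_founders = 60L, n_samples = 120L, n_chromosomes = 1L,
                      chrom_length_bp = 5e7, n_sites_per_chrom = 5000L,
                      annotation_proportions = c(high = 0.05, moderate = 0.15,
                                                 low = 0.1, modifier = 0.7),
                      seed = s)
    pop <- breed_population(simulate_founders(cfg), cfg)
    ann <- assign_annotations(pop$sites, cfg, seed = s + 50)
    hm <- ann$impact_class %in% c("high", "moderate")
    mean(ann$maf[hm] <= 0.03)
  })
  expect_true(all(abs(shares - 0.15) < 0.03))
})

test_that("array-site ascertainment is MAF-weighted, sized and deterministic", {
  cfg <- small_cfg()
  pop <- breed_population(simulate_founders(cfg), cfg)
  s1 <- select_array_sites(pop$sites, 0.1, seed = 4)
  expect_equal(sum(s1$on_array), sum(tapply(s1$on_array, s1$chrom, sum)))
  for (cc in unique(s1$chrom))
    expect_equal(sum(s1$on_array[s1$chrom == cc]),
                 round(0.1 * sum(s1$chrom == cc)))
  expect_gt(mean(s1$maf[s1$on_array]), mean(s1$maf))
  expect_identical(select_array_sites(pop$sites, 0.1, seed = 4)$on_array,
                   s1$on_array)
  expect_error(select_array_sites(pop$sites, 0.002, seed = 4), "< 2")
  # near-total ascertainment leaves a tiny but valid imputation set
  s99 <- select_array_sites(pop$sites, 0.99, seed = 4)
  expect_true(sum(!s99$on_array) >= 0)
})

test_that("the default spectrum keeps the rare segregating fraction near 13.5%", {
  fr <- sapply(1:10, function(s) {
    cfg <- sim_config(seed = s)
    pop <- breed_population(simulate_founders(cfg), cfg)
    rare_fraction(pop$sites$maf)
  })
  expect_true(all(fr >= 0.115 & fr <= 0.155))
})
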